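# Gene-ontology-style overrepresentation of protein lists against GMT
# collections.

#' Gene-set overrepresentation with Z / FDR / minimum-overlap pruning
#'
#' Per gene set, a one-tailed Fisher exact (hypergeometric) test of the
#' overlap between the foreground and the set, both intersected with the
#' background; BH adjustment across all tested sets (sets with no member
#' in the background are skipped). A set passes the pruning filter when
#' its hypergeometric Z exceeds `z_min`, its BH q is below `q_max`, and
#' the overlap holds at least `min_genes` genes. The minimum-gene rule is
#' applied to the overlap by default (`min_on = "overlap"`), i.e. a hit
#' must be supported by at least that many foreground genes; `min_on =
#' "set"` applies it to the set size instead.
#'
#' @param foreground gene symbols (or protein ids, symbols are extracted)
#'   of interest; must be a subset of the background
#' @param background symbol universe
#' @param gmt gene-set collection from [read_gmt()] / [simulate_gmt()]
#' @param min_genes minimum genes for the pruning filter
#' @param z_min minimum hypergeometric Z for the pruning filter
#' @param q_max maximum BH q for the pruning filter
#' @param min_on apply `min_genes` to the `"overlap"` (default) or the
#'   `"set"` size
#' @return data.frame: set_id, description, overlap stats, z_score,
#'   p_one_tailed, q_bh, pass
#' @export
go_fet <- function(foreground, background, gmt, min_genes = 5L,
                   z_min = 1.96, q_max = 0.05,
                   min_on = c("overlap", "set")) {
  min_on <- match.arg(min_on)
  if (!length(foreground)) stopf("foreground is empty")
  fg <- unique(gene_symbols(foreground))
  bg <- unique(gene_symbols(background))
  offenders <- setdiff(fg, bg)
  if (length(offenders))
    stopf("foreground not a subset of background: %s",
          paste(utils::head(offenders, 5L), collapse = ", "))
  desc <- attr(gmt, "descriptions") %||% stats::setNames(rep(NA_character_, length(gmt)), names(gmt))
  rows <- list()
  for (id in names(gmt)) {
    members <- intersect(unique(toupper(gmt[[id]])), bg)
    if (!length(members)) next  # set absent from background: skipped
    rows[[id]] <- enrichment_rows(id, "foreground", members, fg, bg)
  }
  if (!length(rows)) return(data.frame())
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$description <- unname(desc[tab$set_id])
  tab$q_bh <- bh_adjust(tab$p_one_tailed)
  size_for_min <- if (min_on == "overlap") tab$overlap_k else tab$set_size_K
  tab$pass <- tab$z_score > z_min & !is.na(tab$q_bh) & tab$q_bh < q_max &
    size_for_min >= min_genes
  tab[order(tab$p_one_tailed, tab$set_id), , drop = FALSE]
}
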