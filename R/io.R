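# Data model and tab-separated readers/writers.
#
# An abundance matrix is a plain numeric matrix (proteins x samples) with
# rownames "UniProtID|GeneSymbol", colnames sample ids, NA as the missing
# marker and a "scale" attribute in {"raw", "normalized", "log2", "z"}.
# Raw/normalized values must be strictly positive where observed; log2/z
# values finite where observed.

ABN_SCALES <- c("raw", "normalized", "log2", "z")
DIAGNOSIS_LEVELS <- c("Control", "AD", "AsymAD", "GIS")

#' Construct a validated abundance matrix
#'
#' @param values numeric matrix, proteins in rows (rownames are
#'   `"UniProtID|GeneSymbol"` ids) and samples in columns. `NA` marks a
#'   missing measurement; zeros are not a valid missing marker.
#' @param scale one of `"raw"`, `"normalized"`, `"log2"`, `"z"`
#' @return the matrix with its `scale` attribute set
#' @export
abundance_matrix <- function(values, scale = c("raw", "normalized", "log2", "z")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("abundance values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("abundance matrix needs protein rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stopf("duplicate protein id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  obs <- values[!is.na(values)]
  if (scale %in% c("raw", "normalized")) {
    if (any(obs <= 0))
      stopf("%s-scale abundances must be strictly positive where observed", scale)
  } else if (any(!is.finite(obs))) {
    stopf("%s-scale abundances must be finite where observed", scale)
  }
  attr(values, "scale") <- scale
  values
}

#' Get or set the scale flag of an abundance matrix
#' @param M abundance matrix
#' @return the scale string
#' @export
abn_scale <- function(M) attr(M, "scale") %||% "raw"

#' @rdname abn_scale
#' @param value new scale flag
#' @export
`abn_scale<-` <- function(M, value) {
  abundance_matrix(M, scale = value)
}

#' Read a protein-by-sample abundance matrix from TSV
#'
#' First column holds protein ids, header row the sample ids; empty cells
#' and "NA" are missing. Optionally zeros are converted to missing, the
#' convention for label-free search-engine exports where an intensity of 0
#' means not detected.
#'
#' @param path file path
#' @param scale declared scale of the stored values
#' @param zero_as_missing convert 0 values to `NA` on load
#' @return abundance matrix
#' @export
read_abundance_matrix <- function(path, scale = c("raw", "normalized", "log2", "z"),
                                  zero_as_missing = FALSE) {
  scale <- match.arg(scale)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stopf("abundance file needs an id column plus >=1 sample: %s", path)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate protein id(s): %s", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  missing_mask <- cells == "" | cells == "NA" | is.na(cells)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !missing_mask, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric cell at row %d (protein %s), column %s",
          bad[1L, 1L], ids[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]])
  }
  num[missing_mask] <- NA_real_
  if (zero_as_missing) num[!is.na(num) & num == 0] <- NA_real_
  rownames(num) <- ids
  colnames(num) <- colnames(cells)
  abundance_matrix(num, scale = scale)
}

#' Write an abundance matrix as TSV
#'
#' Values are serialized with 17 significant digits so a write/read cycle
#' is value-identical.
#'
#' @param M abundance matrix
#' @param path output path
#' @param id_header header of the protein id column
#' @export
write_abundance_matrix <- function(M, path, id_header = "protein_id") {
  txt <- apply(M, 2L, format_num)
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(M), dimnames = dimnames(M))
  df <- data.frame(rownames(M), txt, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_header, colnames(M))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `set_label`, `batch_label`, `is_gis`,
#' `diagnosis`. A `channel_label` column and arbitrary covariate columns
#' (e.g. age, sex, PMI) are carried through. GIS (pooled global internal
#' standard) rows carry the sentinel diagnosis `"GIS"`.
#'
#' @param path TSV path
#' @return data.frame with typed columns
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "set_label", "batch_label", "is_gis", "diagnosis")
  for (col in required) {
    if (!col %in% colnames(df)) stopf("missing column %s", col)
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stopf("duplicate sample_id(s): %s", paste(dup, collapse = ", "))
  df$is_gis <- parse_logical(df$is_gis, "is_gis")
  bad <- setdiff(unique(df$diagnosis), DIAGNOSIS_LEVELS)
  if (length(bad))
    stopf("unknown diagnosis value(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(DIAGNOSIS_LEVELS, collapse = ", "))
  if (any(df$is_gis & df$diagnosis != "GIS"))
    stopf("GIS samples must carry the sentinel diagnosis \"GIS\"")
  validate_sample_sheet(df)
  df
}

parse_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  up <- toupper(as.character(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) stopf("column %s is not interpretable as logical", name)
  out
}

validate_sample_sheet <- function(sheet) {
  counts <- table(sheet$batch_label)
  if (any(counts < 1L)) stopf("every batch must contain at least one sample")
  invisible(sheet)
}

#' Write a sample sheet as TSV
#' @param sheet sample sheet data.frame
#' @param path output path
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TRAIT_COLUMNS <- c("MoCA", "CSF_Abeta42", "CSF_tTau", "CSF_pTau181",
                   "tTau_Abeta_ratio", "plasma_pTau181")

#' Read a biomarker trait table
#'
#' Columns: `sample_id` plus the six AD-related measures (MoCA cognition
#' score, CSF amyloid-beta 1-42, CSF total tau, CSF pTau181, the
#' tTau/Abeta42 ratio, plasma pTau181). Missing values allowed. Where both
#' components are present the stored ratio must equal `CSF_tTau /
#' CSF_Abeta42` (1e-9 relative).
#'
#' @param path TSV path
#' @return data.frame
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stopf("missing column sample_id")
  for (col in TRAIT_COLUMNS) {
    if (!col %in% colnames(df)) stopf("missing column %s", col)
    df[[col]] <- as.numeric(df[[col]])
  }
  df$sample_id <- as.character(df$sample_id)
  validate_trait_table(df)
  df
}

validate_trait_table <- function(traits) {
  both <- !is.na(traits$CSF_tTau) & !is.na(traits$CSF_Abeta42) &
    !is.na(traits$tTau_Abeta_ratio)
  if (any(both)) {
    expect <- traits$CSF_tTau[both] / traits$CSF_Abeta42[both]
    rel <- abs(traits$tTau_Abeta_ratio[both] - expect) / pmax(abs(expect), 1e-300)
    if (any(rel > 1e-9))
      stopf("tTau_Abeta_ratio inconsistent with CSF_tTau / CSF_Abeta42 for sample %s",
            traits$sample_id[both][which(rel > 1e-9)[1L]])
  }
  invisible(traits)
}

#' Write a trait table as TSV
#' @param traits trait table data.frame
#' @param path output path
#' @export
write_trait_table <- function(traits, path) {
  out <- traits
  for (col in TRAIT_COLUMNS) out[[col]] <- format_num(traits[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reference co-expression network object
#'
#' @param membership named character vector mapping protein id to module id
#'   (values must be module ids or `"grey"`)
#' @param eigenproteins module x sample numeric matrix of eigenproteins;
#'   each row must have mean 0 and unit variance across samples (1e-6)
#' @param module_labels optional named character vector of free-text module
#'   annotations
#' @return a `network_reference` list
#' @export
network_reference <- function(membership, eigenproteins, module_labels = NULL) {
  if (is.null(names(membership))) stopf("membership must be named by protein id")
  if (is.null(rownames(eigenproteins))) stopf("eigenprotein rows must be named by module")
  module_ids <- rownames(eigenproteins)
  bad <- setdiff(unique(membership), c(module_ids, "grey"))
  if (length(bad))
    stopf("membership refers to unknown module(s): %s", paste(bad, collapse = ", "))
  mu <- rowMeans(eigenproteins)
  sdv <- apply(eigenproteins, 1L, stats::sd)
  if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 1e-6))
    stopf("eigenprotein rows must be standardized (mean 0, sd 1 within 1e-6)")
  structure(list(module_ids = module_ids,
                 membership = membership,
                 eigenproteins = eigenproteins,
                 module_labels = module_labels),
            class = "network_reference")
}

#' Read a network reference from its two TSV files
#' @param membership_path TSV with columns protein_id, module_id
#' @param eigenprotein_path TSV, module rows x sample columns
#' @return `network_reference`
#' @export
read_network_reference <- function(membership_path, eigenprotein_path) {
  mem <- utils::read.table(membership_path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("protein_id", "module_id") %in% colnames(mem)))
    stopf("membership file needs columns protein_id, module_id")
  eig <- utils::read.table(eigenprotein_path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "", check.names = FALSE,
                           row.names = 1L)
  eig <- as.matrix(eig)
  labels <- NULL
  if ("module_label" %in% colnames(mem)) {
    labels <- tapply(mem$module_label, mem$module_id, `[`, 1L)
  }
  network_reference(stats::setNames(mem$module_id, mem$protein_id), eig, labels)
}

#' Write a network reference as two TSV files
#' @param ref `network_reference`
#' @param membership_path output path for the membership table
#' @param eigenprotein_path output path for the eigenprotein matrix
#' @export
write_network_reference <- function(ref, membership_path, eigenprotein_path) {
  mem <- data.frame(protein_id = names(ref$membership),
                    module_id = unname(ref$membership),
                    stringsAsFactors = FALSE)
  utils::write.table(mem, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  eig <- ref$eigenproteins
  txt <- apply(eig, 2L, format_num)
  df <- data.frame(module_id = rownames(eig), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, eigenprotein_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ref)
}

#' Read a GMT gene-set collection
#'
#' Standard 3+-field format: `set_id TAB description TAB gene1 TAB ...`.
#' Gene symbols are upper-cased and de-duplicated; insertion order of sets
#' is preserved.
#'
#' @param path GMT path
#' @return named list of character vectors with a `descriptions` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stopf("GMT line %d has fewer than 3 fields", i)
    id <- fields[[1L]]
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("GMT line %d (%s) has no member genes", i, id)
    sets[[id]] <- genes
    desc[[id]] <- fields[[2L]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute)
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% stats::setNames(rep("NA", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "NA", sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
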