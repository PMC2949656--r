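# All tabular interchange is UTF-8 TSV with one header row; missing numeric
# values are encoded "NA". Genomic positions are 1-based bp.

.read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", ...)
}

.write_tsv <- function(df, path, ...) {
  # full-precision numeric formatting so write -> read is the identity
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, ...)
}

.stop_dup <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d))
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(d, 5L), collapse = ", ")), call. = FALSE)
}

#' Validate a log2 expression matrix
#'
#' An expression matrix is a numeric matrix of log2 intensities with unique,
#' non-empty probe ids as rownames and sample ids as colnames. Values may be
#' `NA` (flagged missing) but never infinite.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @return The matrix, invisibly, after validation.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry probe ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  .stop_dup(rownames(values), "probe ids")
  .stop_dup(colnames(values), "sample ids")
  if (any(is.infinite(values)))
    stop("expression matrix contains non-finite values that are not NA",
         call. = FALSE)
  invisible(values)
}

#' Read a probes-by-samples expression matrix from TSV
#'
#' First column holds probe ids, header row holds sample ids, body is numeric
#' (log2 scale by convention).
#'
#' @param path TSV file path.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a probe id column and >=1 sample")
  probe_ids <- df[[1L]]
  .stop_dup(probe_ids, "probe ids")
  sample_ids <- colnames(df)[-1L]
  .stop_dup(sample_ids, "sample ids")
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  missing_ok <- is.na(body) | body %in% c("NA", "")
  bad <- which(is.na(num) & !missing_ok, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at probe '%s', sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]],
                 probe_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
         call. = FALSE)
  dimnames(num) <- list(probe_ids, sample_ids)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV
#'
#' @param values validated expression matrix.
#' @param path output path.
#' @param id_column name of the probe id column, first in the header.
#' @export
write_expression_matrix <- function(values, path, id_column = "probe_id") {
  validate_expression_matrix(values)
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  .write_tsv(df, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `gene_symbol`, `unigene_id`, `entrez_id`,
#' `is_control` (logical or 0/1). Identifier fields may be empty.
#'
#' @param path TSV file path.
#' @return data.frame with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  df <- .read_tsv(path)
  need <- c("probe_id", "gene_symbol", "unigene_id", "entrez_id", "is_control")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("probe annotation missing columns: ", paste(miss, collapse = ", "))
  .stop_dup(df$probe_id, "probe ids")
  df$is_control <- as.logical(df$is_control)
  df
}

#' @rdname read_probe_annotation
#' @param annotation probe annotation data.frame.
#' @export
write_probe_annotation <- function(annotation, path) {
  .write_tsv(annotation, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Columns: `sample_id`, `cowden_status` (`cowden`/`non_cowden`),
#' `germline_mutation` (free text); any further columns are treated as class
#' label schemes.
#'
#' @param path TSV file path.
#' @return data.frame, one row per sample.
#' @export
read_sample_annotation <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("sample_id", "cowden_status") %in% colnames(df)))
    stop("sample annotation needs columns sample_id and cowden_status")
  .stop_dup(df$sample_id, "sample ids")
  bad <- setdiff(unique(df$cowden_status), c("cowden", "non_cowden"))
  if (length(bad))
    stop("cowden_status must be 'cowden' or 'non_cowden'; found: ",
         paste(bad, collapse = ", "))
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member lists are
#' de-duplicated preserving first occurrence.
#'
#' @param path GMT file path.
#' @return Named list of character member vectors; set descriptions are kept
#'   in the `"description"` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 member",
                   i, length(f)), call. = FALSE)
    name <- f[[1L]]
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    sets[[name]] <- unique(members)
    descs[[name]] <- f[[2L]]
  }
  attr(sets, "description") <- descs
  sets
}

#' @rdname read_gene_sets
#' @param sets named list of member vectors (as returned by [read_gene_sets()]).
#' @export
write_gene_sets <- function(sets, path) {
  descs <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subtype centroid table
#'
#' TSV with a mandatory header comment `# namespace: <symbol|unigene|entrez>`
#' declaring the identifier namespace of the gene column, then a header row
#' `gene_id<TAB><subtype1>...` and one numeric row per gene.
#'
#' @param path TSV file path.
#' @return Numeric gene-by-subtype matrix with the namespace in the
#'   `"namespace"` attribute.
#' @export
read_centroids <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*namespace:\\s*(\\w+)\\s*$", first))[[1L]]
  if (length(m) < 2L)
    stop("centroid file must declare its identifier namespace in a first line '# namespace: <symbol|unigene|entrez>'",
         call. = FALSE)
  ns <- m[[2L]]
  if (!ns %in% c("symbol", "unigene", "entrez"))
    stop("unknown centroid namespace: ", ns)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE, check.names = FALSE)
  .stop_dup(df[[1L]], "centroid gene ids")
  .stop_dup(colnames(df)[-1L], "subtype names")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("centroid values must be numeric")
  rownames(vals) <- df[[1L]]
  attr(vals, "namespace") <- ns
  vals
}

#' @rdname read_centroids
#' @param centroids gene-by-subtype matrix with a `"namespace"` attribute.
#' @export
write_centroids <- function(centroids, path) {
  ns <- attr(centroids, "namespace")
  if (is.null(ns)) stop("centroid matrix lacks a 'namespace' attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# namespace: %s", ns), con)
  df <- data.frame(gene_id = rownames(centroids), centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a long-format aCGH clone table
#'
#' Columns: `clone_id`, `chromosome`, `position` (1-based bp), `tumor_id`,
#' `cy3`, `cy5`, `snr`, `valid` (0/1). Each row is one spot measurement;
#' clones are typically spotted in quadruplicate per tumor.
#'
#' @param path TSV file path.
#' @return `acgh_experiment`: a list with `clones` (clone_id, chromosome,
#'   position) and `spots` (all spot-level measurements).
#' @export
read_clone_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("clone_id", "chromosome", "position", "tumor_id",
            "cy3", "cy5", "snr", "valid")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clone table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$position < 0)) stop("clone positions must be non-negative")
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.numeric(df$position)
  for (col in c("cy3", "cy5", "snr")) df[[col]] <- as.numeric(df[[col]])
  clones <- unique(df[, c("clone_id", "chromosome", "position")])
  rownames(clones) <- NULL
  .stop_dup(clones$clone_id, "clone ids (conflicting positions)")
  df$valid <- as.logical(df$valid)
  structure(list(clones = clones,
                 spots = df[, c("clone_id", "tumor_id", "cy3", "cy5",
                                "snr", "valid")]),
            class = "acgh_experiment")
}

#' @rdname read_clone_table
#' @param experiment an `acgh_experiment`.
#' @export
write_clone_table <- function(experiment, path) {
  stopifnot(inherits(experiment, "acgh_experiment"))
  df <- experiment$spots
  i <- match(df$clone_id, experiment$clones$clone_id)
  df$chromosome <- experiment$clones$chromosome[i]
  df$position <- experiment$clones$position[i]
  df <- df[, c("clone_id", "chromosome", "position", "tumor_id",
               "cy3", "cy5", "snr", "valid")]
  df$valid <- as.integer(df$valid)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a centromere / chromosome-length map
#'
#' Columns: `chromosome`, `centromere` (bp), `length` (bp); the centromere
#' must lie strictly inside the chromosome.
#'
#' @param path TSV file path.
#' @return data.frame, one row per chromosome.
#' @export
read_centromeres <- function(path) {
  df <- .read_tsv(path)
  need <- c("chromosome", "centromere", "length")
  if (!all(need %in% colnames(df)))
    stop("centromere map needs columns chromosome, centromere, length")
  df$chromosome <- as.character(df$chromosome)
  df$centromere <- as.numeric(df$centromere)
  df$length <- as.numeric(df$length)
  .stop_dup(df$chromosome, "chromosomes")
  bad <- which(!(df$centromere > 0 & df$centromere < df$length))
  if (length(bad))
    stop("centromere must satisfy 0 < centromere < length; offending chromosome: ",
         df$chromosome[bad[1L]], call. = FALSE)
  df
}

#' @rdname read_centromeres
#' @param map centromere map data.frame.
#' @export
write_centromeres <- function(map, path) {
  .write_tsv(map, path)
  invisible(path)
}

#' Read an immunohistochemistry score table
#'
#' Wide per-tumour format mirroring the study's summary table: columns
#' `sample_id`, `cowden_disease` (Yes/No), `pten_germline`, `age`,
#' `histology`, `grade`, `apocrine_features` (Yes/No), then one column per
#' marker (AR, ER, PR, GCDFP15, GGT1, PTEN scored 0/1/2; ERBB2 scored
#' 0/+/++/+++ by Herceptest, `nd` for not done).
#'
#' @param path TSV file path.
#' @return data.frame, one row per tumour.
#' @export
read_ihc_table <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  if (!"sample_id" %in% colnames(df)) stop("IHC table needs a sample_id column")
  .stop_dup(df$sample_id, "sample ids")
  df
}
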