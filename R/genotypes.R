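#' Construct a genotype matrix object
#'
#' A `genotype_matrix` holds an n x p matrix of binary dominant marker
#' calls (0/1, `NA` allowed) for n lines, plus per-marker allele
#' frequencies once the matrix has been imputed.
#'
#' @param X numeric matrix with entries in \{0, 1, NA\}.
#' @param line_ids character vector of unique line identifiers (rows).
#' @param marker_ids character vector of unique marker identifiers (columns).
#' @return An object of class `genotype_matrix` with elements `X`,
#'   `line_ids`, `marker_ids`, `q` (allele frequencies, `NULL` until
#'   [impute_genotypes] is run) and `imputed` (logical).
#' @export
genotype_matrix <- function(X, line_ids = rownames(X),
                            marker_ids = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(X)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(X)))
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(line_ids))
    stop("duplicate line ids: ",
         paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  if (length(line_ids) != nrow(X) || length(marker_ids) != ncol(X))
    stop("id lengths do not match matrix dimensions")
  bad <- !(X %in% c(0, 1)) & !is.na(X)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(X)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary genotype value at line '%s', marker '%s'",
                 line_ids[idx[1]], marker_ids[idx[2]]))
  }
  storage.mode(X) <- "double"
  dimnames(X) <- list(line_ids, marker_ids)
  structure(list(X = X, line_ids = line_ids, marker_ids = marker_ids,
                 q = NULL, imputed = FALSE, removed_markers = character(0)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers (%s, %d missing)\n",
              nrow(x$X), ncol(x$X),
              if (x$imputed) "imputed" else "raw",
              sum(is.na(x$X))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$X)

#' Extract the marker matrix from a genotype object
#'
#' @param G a `genotype_matrix` or a plain numeric matrix.
#' @return numeric matrix, lines in rows.
#' @export
marker_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$X else as.matrix(G)
}

#' Read a genotype file
#'
#' Delimited text with marker ids in the header row, line ids in the first
#' column and cells in \{0, 1, NA\}. Missing cells are preserved.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("genotype file needs a line-id column and markers")
  line_ids <- df[[1]]
  marker_ids <- colnames(df)[-1]
  M <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(M), nrow(M), ncol(M)))
  bad <- (!is.na(M) & is.na(num)) | (!is.na(num) & !(num %in% c(0, 1)))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell '%s' at line '%s', marker '%s'",
                 M[idx[1], idx[2]], line_ids[idx[1]], marker_ids[idx[2]]))
  }
  genotype_matrix(num, line_ids, marker_ids)
}

#' Write a genotype file
#'
#' @param G a [genotype_matrix].
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_genotypes <- function(G, path, sep = "\t") {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(line_id = G$line_ids, G$X, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns `line_id`, `env`, `trait`, `value`.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return data.frame with those four columns.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("line_id", "env", "trait", "value")
  if (!all(need %in% colnames(df)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$line_id <- as.character(df$line_id)
  df$env <- as.character(df$env)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) stop("non-finite phenotype values")
  key <- paste(df$line_id, df$env, df$trait)
  if (anyDuplicated(key))
    stop("duplicated (line_id, env, trait) records")
  df
}

#' Write a phenotype table
#' @param pheno data.frame with columns line_id, env, trait, value.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_phenotypes <- function(pheno, path, sep = "\t") {
  write.table(pheno[, c("line_id", "env", "trait", "value")], path,
              sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing genotypes and compute allele frequencies
#'
#' Missing calls are replaced by the marker (column) mean, which for a 0/1
#' dominant marker is its allele frequency estimate; monomorphic markers
#' (frequency 0 or 1 after imputation) carry no information and are
#' removed.
#'
#' @param G a [genotype_matrix].
#' @return an imputed [genotype_matrix] with `q` filled in and
#'   monomorphic markers dropped (ids recorded in `removed_markers`).
#' @export
impute_genotypes <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$X
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0))
    stop("marker(s) with no observed calls: ",
         paste(G$marker_ids[n_obs == 0], collapse = ", "))
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) {
    X[is.na(X[, j]), j] <- cm[j]
  }
  q <- colMeans(X)
  mono <- q <= 0 | q >= 1
  removed <- G$marker_ids[mono]
  if (any(mono)) {
    X <- X[, !mono, drop = FALSE]
    q <- q[!mono]
  }
  keep_ids <- G$marker_ids[!mono]
  dimnames(X) <- list(G$line_ids, keep_ids)
  structure(list(X = X, line_ids = G$line_ids, marker_ids = keep_ids,
                 q = unname(q), imputed = TRUE, removed_markers = removed),
            class = "genotype_matrix")
}
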