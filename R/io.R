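# Plain-text I/O: connectivity matrices (square TSV, no header), cohort
# tables, network labels, gradients (TSV + JSON sidecar).

#' Read a connectivity matrix from TSV
#'
#' Square, numeric, headerless TSV; invariants (symmetry, unit diagonal,
#' values in [-1, 1]) are validated on read.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop("matrix in '", path, "' is not square: ", nrow(m), "x", ncol(m))
  }
  validate_connectivity(m, what = paste0("matrix in '", path, "'"))
  m
}

#' Write a connectivity matrix to TSV
#'
#' Full precision (round-trips losslessly to < 1e-12).
#'
#' @param matrix Matrix to write.
#' @param path Destination.
#' @export
write_matrix <- function(matrix, path) {
  utils::write.table(format(matrix, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a cohort table
#'
#' TSV with header columns subject_id, group, age, sex, site, mean_fd.
#'
#' @param path File path.
#' @return data.frame with typed columns.
#' @export
read_cohort <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "site", "mean_fd")
  if (!all(need %in% names(d))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(d$mean_fd < 0)) stop("mean_fd must be >= 0")
  if (anyDuplicated(d$subject_id)) stop("subject_id must be unique")
  d$group <- factor(d$group, levels = c("NC", "SCZ"))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$site <- factor(d$site)
  d
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write parcel-to-network labels
#'
#' Two-column TSV (parcel_id, network) with header.
#'
#' @param path File path.
#' @return Named character vector (names = parcel ids).
#' @export
read_network_labels <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stats::setNames(d$network, d$parcel_id)
}

#' @rdname read_network_labels
#' @param labels Named character vector.
#' @export
write_network_labels <- function(labels, path) {
  utils::write.table(data.frame(parcel_id = names(labels), network = labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gradient set (TSV scores + JSON sidecar)
#'
#' @param gradients `gradient_set`.
#' @param path Scores TSV path; the sidecar goes to `<path>.json`.
#' @export
write_gradients <- function(gradients, path) {
  utils::write.table(format(gradients$scores, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(variance_ratio = gradients$variance_ratio,
                            aligned = gradients$aligned),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
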