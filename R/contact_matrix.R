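#' Binned contact matrix
#'
#' A symmetric, non-negative matrix of contact counts for one chromosome (or a
#' simulated region) at a fixed bin resolution, with an optional set of masked
#' (invalid) bins. Masked bins are excluded from all averages downstream.
#'
#' @param values square numeric matrix of contact counts (symmetric,
#'   non-negative; small asymmetries from file round-trips are symmetrized).
#' @param resolution bin size in bp.
#' @param chrom chromosome/region identifier.
#' @param mask integer vector of 1-based masked bin indices.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, resolution, chrom = "chrS", mask = integer()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (any(values < 0, na.rm = TRUE)) stop("contact matrix must be non-negative")
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (asym > 1e-8 * max(abs(values), 1)) stop("contact matrix must be symmetric")
  values <- (values + t(values)) / 2
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) && (min(mask) < 1 || max(mask) > nrow(values)))
    stop("mask indices out of range")
  structure(
    list(values = values, resolution = as.numeric(resolution),
         chrom = chrom, mask = mask),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<%s> %s: %d bins @ %g bp, %d masked\n",
              class(x)[1], x$chrom, nrow(x$values), x$resolution,
              length(x$mask)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$values)

n_bins <- function(m) nrow(m$values)

valid_bins <- function(m) setdiff(seq_len(n_bins(m)), m$mask)

#' Distance-decay expectation of a contact matrix
#'
#' For each genomic separation `d` (in bins), the mean contact count over all
#' unmasked bin pairs at that separation. Diagonals with no unmasked entry are
#' `NA` and propagate as masked in the obs/exp map.
#'
#' @param m a [contact_matrix()].
#' @return numeric vector of length `nbins`, `expected[d + 1]` being the mean
#'   at separation `d` bins.
#' @export
compute_expected <- function(m) {
  v <- m$values
  n <- nrow(v)
  ok <- !(seq_len(n) %in% m$mask)
  exp_d <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    keep <- ok[i] & ok[i + d]
    if (any(keep))
      exp_d[d + 1] <- mean(v[cbind(i[keep], i[keep] + d)])
  }
  exp_d
}

#' Observed/expected (distance-normalized) contact map
#'
#' Divides each entry by the mean contact count at its genomic separation.
#' Masked bins and separations with undefined expectation become `NA`.
#' The mean over each unmasked diagonal of the result is 1 by construction,
#' and the map is invariant to global rescaling of the observed counts.
#'
#' @param m a [contact_matrix()].
#' @param expected optional precomputed [compute_expected()] vector.
#' @return an object of classes `obs_exp_matrix`, `contact_matrix`; entries
#'   are the normalized contacts `c_ij`.
#' @export
compute_obs_exp <- function(m, expected = NULL) {
  if (is.null(expected)) expected <- compute_expected(m)
  n <- nrow(m$values)
  d <- abs(row(m$values) - col(m$values))
  e <- matrix(expected[d + 1], n, n)
  vals <- m$values / e
  if (length(m$mask)) {
    vals[m$mask, ] <- NA_real_
    vals[, m$mask] <- NA_real_
  }
  out <- m
  out$values <- vals
  out$expected <- expected
  class(out) <- c("obs_exp_matrix", "contact_matrix")
  out
}

#' Write a contact matrix as plain dense text
#'
#' Header lines (`#chrom`, `#resolution`, `#mask`) followed by the
#' whitespace-separated dense matrix at full double precision, so that a
#' read/write round trip is exact.
#'
#' @param m a [contact_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#chrom\t", m$chrom),
    paste0("#resolution\t", format(m$resolution, digits = 17)),
    paste0("#mask\t", paste(m$mask, collapse = ","))), con)
  rows <- apply(m$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(rows, con)
  invisible(path)
}

#' Read a dense-text contact matrix written by [write_contact_matrix()]
#' @param path input file.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path) {
  hdr <- readLines(path, n = 3)
  fields <- strsplit(hdr, "\t")
  chrom <- fields[[1]][2]
  resolution <- as.numeric(fields[[2]][2])
  mask <- fields[[3]]
  mask <- if (length(mask) < 2 || !nzchar(mask[2])) integer() else
    as.integer(strsplit(mask[2], ",")[[1]])
  vals <- as.matrix(read.table(path, skip = 3))
  dimnames(vals) <- NULL
  contact_matrix(vals, resolution, chrom, mask)
}
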