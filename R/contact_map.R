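#' Construct and validate a contact probability map
#'
#' A `contact_map` is a symmetric matrix of pairwise contact probabilities
#' `P[i, j]` in \[0, 1\] with unit diagonal, together with genomic metadata.
#' Bin `b` (0-based) covers the half-open genomic interval
#' `[start_bp + b * resolution_bp, start_bp + (b + 1) * resolution_bp)`.
#'
#' @param matrix Square numeric matrix of contact probabilities. Symmetrized
#'   as `(M + t(M))/2` (with a warning if the maximum asymmetry exceeds 1e-8);
#'   the diagonal is forced to 1 (with a warning if it deviates).
#' @param resolution_bp Genomic bin size in base pairs (200 for
#'   nucleosome-linker beads).
#' @param chrom Chromosome label.
#' @param start_bp 0-based genomic start coordinate of bin 0.
#' @return An object of class `contact_map`: the validated matrix with
#'   metadata attributes `resolution_bp`, `chrom`, `start_bp`.
#' @examples
#' m <- diag(3)
#' cm <- contact_map(m)
#' n_bins(cm)
#' @export
contact_map <- function(matrix, resolution_bp = 200L, chrom = "chr",
                        start_bp = 0L) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(matrix) != ncol(matrix)) {
    stop("contact map must be square, got ", nrow(matrix), " x ", ncol(matrix),
         call. = FALSE)
  }
  if (nrow(matrix) == 0L) stop("contact map must have at least 1 bin", call. = FALSE)
  if (any(!is.finite(matrix))) stop("contact map entries must be finite", call. = FALSE)
  tol <- 1e-9
  if (any(matrix < -tol) || any(matrix > 1 + tol)) {
    stop("contact probabilities must lie in [0, 1]", call. = FALSE)
  }
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-8) {
    warning(sprintf("matrix asymmetry %.3g > 1e-8; symmetrizing as (M + t(M))/2", asym))
  }
  m <- (matrix + t(matrix)) / 2
  if (max(abs(diag(m) - 1)) > tol) {
    warning("diagonal deviates from 1; forcing unit diagonal")
  }
  diag(m) <- 1
  m[m < 0] <- 0
  m[m > 1] <- 1
  dimnames(m) <- NULL
  structure(m,
            resolution_bp = as.integer(resolution_bp),
            chrom = as.character(chrom),
            start_bp = as.integer(start_bp),
            class = c("contact_map", "matrix", "array"))
}

#' @rdname contact_map
#' @param x A `contact_map`.
#' @export
n_bins <- function(x) nrow(x)

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d bins, %s:%d, %d bp/bin\n",
              n_bins(x), attr(x, "chrom"), attr(x, "start_bp"),
              attr(x, "resolution_bp")))
  invisible(x)
}

#' Read a contact probability map from a dense TSV file
#'
#' The file is a whitespace-delimited square numeric matrix, optionally
#' preceded by a metadata header line `#chrom start resolution_bp`.
#'
#' @param path File path.
#' @param format On-disk format; only `"tsv"` (dense whitespace-delimited
#'   matrix) is supported.
#' @return A validated [contact_map()].
#' @export
read_contact_map <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  chrom <- "chr"; start_bp <- 0L; res <- 200L; skip <- 0L
  if (startsWith(first, "#")) {
    parts <- strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]
    if (length(parts) >= 3L) {
      chrom <- parts[1]
      start_bp <- as.integer(parts[2])
      res <- as.integer(parts[3])
    }
    skip <- 1L
  }
  m <- as.matrix(utils::read.table(path, skip = skip, header = FALSE))
  if (!is.numeric(m)) stop("contact map file must be numeric", call. = FALSE)
  contact_map(unname(m), resolution_bp = res, chrom = chrom, start_bp = start_bp)
}

#' Write a contact map to a dense TSV file
#'
#' Entries are printed with enough digits (`%.10g`) that a round-trip through
#' [read_contact_map()] reproduces the matrix to within 1e-9.
#'
#' @param map A [contact_map()].
#' @param path Output path.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, digits = 10L) {
  stopifnot(inherits(map, "contact_map"))
  header <- sprintf("#%s %d %d", attr(map, "chrom"), attr(map, "start_bp"),
                    attr(map, "resolution_bp"))
  body <- apply(unclass(map), 1L, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Identify prominent contacts of a contact map
#'
#' For each genomic separation `s = |i - j| >= 2` the mean `mu_s` and
#' population standard deviation `sigma_s` of all entries at that separation
#' are computed, and a pair is prominent when its probability is at least one
#' standard deviation above the stratum mean, `P >= mu_s + sigma_s`. A
#' zero-variance stratum yields no prominent contacts (the inequality is made
#' strict there: equal entries carry no outlier signal). Separations 0 and 1
#' are excluded because adjacent beads are already chain-bonded.
#'
#' @param map A [contact_map()] with at least 4 bins.
#' @return A tibble with columns `i`, `j` (0-based bin indices, `i < j`) and
#'   `p` (the contact probability), ordered by `(i, j)`.
#' @export
find_prominent_contacts <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  n <- n_bins(map)
  if (n < 4L) stop("need at least 4 bins", call. = FALSE)
  m <- unclass(map)
  out_i <- integer(0); out_j <- integer(0); out_p <- numeric(0)
  for (s in 2:(n - 1L)) {
    idx <- seq_len(n - s)
    vals <- m[cbind(idx, idx + s)]
    mu <- mean(vals)
    sd_pop <- sqrt(mean((vals - mu)^2))
    sel <- if (sd_pop == 0) rep(FALSE, length(vals)) else vals >= mu + sd_pop
    if (any(sel)) {
      out_i <- c(out_i, idx[sel] - 1L)
      out_j <- c(out_j, idx[sel] + s - 1L)
      out_p <- c(out_p, vals[sel])
    }
  }
  res <- tibble::tibble(i = out_i, j = out_j, p = out_p)
  res <- res[order(res$i, res$j), ]
  attr(res, "n_bins") <- n
  res
}

#' Mean contact probability versus genomic separation
#'
#' @param map A [contact_map()].
#' @return A tibble with columns `s` (separation in bins, 0 to `n_bins - 1`)
#'   and `p` (mean probability over all entries at that separation).
#' @export
contact_probability_curve <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  n <- n_bins(map)
  m <- unclass(map)
  p <- vapply(0:(n - 1L), function(s) {
    idx <- seq_len(n - s)
    mean(m[cbind(idx, idx + s)])
  }, numeric(1))
  tibble::tibble(s = 0:(n - 1L), p = p)
}
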