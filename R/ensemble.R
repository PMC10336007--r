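#' Ensembles of polymer conformations
#'
#' An `ensemble` holds one or more conformations of an N-bead chain: a list
#' of N x 3 coordinate matrices (reduced sigma units), an optional
#' per-conformation list of constraint-bond pairs, and a provenance record
#' (force field, integrator parameters, seeds).
#'
#' @param coords List of N x 3 numeric matrices sharing the same N.
#' @param bonds Optional list (same length) of 2-column integer matrices of
#'   0-based constraint-bond pairs, or `NULL`.
#' @param provenance Named list recording how the ensemble was produced.
#' @return An object of class `ensemble`.
#' @export
new_ensemble <- function(coords, bonds = NULL, provenance = list()) {
  stopifnot(is.list(coords), length(coords) >= 1)
  n <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) {
    is.matrix(m) && ncol(m) == 3 && nrow(m) == n && all(is.finite(m))
  }, logical(1))
  if (!all(ok)) stop("all conformations must be finite N x 3 matrices with equal N",
                     call. = FALSE)
  if (!is.null(bonds)) stopifnot(length(bonds) == length(coords))
  structure(list(coords = coords, bonds = bonds, provenance = provenance),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d conformations of %d beads%s\n",
              length(x$coords), n_beads(x),
              if (is.null(x$bonds)) "" else " (with constraint bonds)"))
  invisible(x)
}

#' @rdname new_ensemble
#' @param x An `ensemble`.
#' @export
n_beads <- function(x) nrow(x$coords[[1]])

#' @rdname new_ensemble
#' @export
n_conformations <- function(x) length(x$coords)

#' Write / read an ensemble as plain-text TSV
#'
#' One row per bead per conformation, columns `config`, `bead`, `x`, `y`,
#' `z`; constraint bonds (if any) go to a companion `<path>.bonds.tsv` with
#' columns `config`, `i`, `j`. [read_ensemble_tsv()] inverts the layout.
#'
#' @param ensemble An [new_ensemble()] object.
#' @param path Output TSV path.
#' @return `path` invisibly; for the reader, an `ensemble`.
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble"))
  n <- n_beads(ensemble)
  rows <- purrr::imap(ensemble$coords, function(m, c) {
    data.frame(config = c, bead = seq_len(n) - 1L,
               x = m[, 1], y = m[, 2], z = m[, 3])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(ensemble$bonds)) {
    brows <- purrr::imap(ensemble$bonds, function(b, c) {
      if (is.null(b) || nrow(b) == 0) return(NULL)
      data.frame(config = c, i = b[, 1], j = b[, 2])
    })
    brows <- Filter(Negate(is.null), brows)
    if (length(brows)) {
      utils::write.table(do.call(rbind, brows), paste0(path, ".bonds.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @export
read_ensemble_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  coords <- lapply(split(df, df$config), function(d) {
    d <- d[order(d$bead), ]
    unname(as.matrix(d[, c("x", "y", "z")]))
  })
  names(coords) <- NULL
  bonds <- NULL
  bpath <- paste0(path, ".bonds.tsv")
  if (file.exists(bpath)) {
    bd <- utils::read.table(bpath, header = TRUE, sep = "\t")
    bonds <- lapply(seq_along(coords), function(c) {
      sub <- bd[bd$config == c, c("i", "j"), drop = FALSE]
      unname(as.matrix(sub))
    })
  }
  new_ensemble(coords, bonds = bonds)
}

#' Export a single conformation in XYZ format
#'
#' @param coords N x 3 coordinate matrix.
#' @param path Output path.
#' @param element Atom label to use.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(coords, path, element = "C") {
  n <- nrow(coords)
  lines <- c(as.character(n), "polymer conformation",
             sprintf("%s %.6f %.6f %.6f", element,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}
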