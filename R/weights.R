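#' Spatial weight matrices
#'
#' An `eco_weights` object is a nonnegative square matrix with a zero
#' diagonal, an ordered vector of region ids, and a flag recording whether
#' rows have been standardized to sum to one.  All spatial routines in the
#' package (`global_morans_i()`, `spatial_lag()`, `fit_sdm()`, the spatial
#' Markov matrices) take one of these.
#'
#' @param w square numeric matrix, nonnegative, zero diagonal.
#' @param ids character vector of region identifiers, one per row.
#' @param standardized logical; have rows been scaled to sum to one?
#' @return An `eco_weights` object.
#' @export
eco_weights <- function(w, ids = NULL, standardized = FALSE) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) {
    abort(sprintf("weight matrix must be square, got %d x %d", nrow(w), ncol(w)),
          class = "ecoeff_format_error")
  }
  if (any(w < 0)) {
    abort("weight matrix must be nonnegative", class = "ecoeff_domain_error")
  }
  if (any(diag(w) != 0)) {
    warn("nonzero diagonal entries in weight matrix were set to zero")
    diag(w) <- 0
  }
  ids <- as.character(ids %||% rownames(w) %||% paste0("R", seq_len(nrow(w))))
  if (length(ids) != nrow(w)) {
    abort("length(ids) must equal nrow(w)", class = "ecoeff_format_error")
  }
  dimnames(w) <- list(ids, ids)
  structure(list(ids = ids, w = w, standardized = isTRUE(standardized)),
            class = "eco_weights")
}

#' @export
print.eco_weights <- function(x, ...) {
  cat(sprintf("<eco_weights> %d regions, %s, %d nonzero links\n",
              length(x$ids), if (x$standardized) "row-standardized" else "raw",
              sum(x$w != 0)))
  invisible(x)
}

#' @export
dim.eco_weights <- function(x) dim(x$w)

#' Row-standardize a spatial weight matrix
#'
#' Divides every row with a positive sum by that sum so nonzero rows sum to
#' one.  Zero rows (isolated regions) are left untouched and reported via a
#' warning, because a spatial lag at an isolated region is identically zero
#' and downstream statistics should know about it.
#'
#' @param W an [eco_weights] object or square matrix.
#' @return A row-standardized `eco_weights` object. Idempotent.
#' @export
row_standardize <- function(W) {
  W <- as_eco_weights(W)
  rs <- rowSums(W$w)
  zero <- which(rs == 0)
  if (length(zero)) {
    warn(sprintf("isolated regions with zero row sums left unstandardized: %s",
                 paste(W$ids[zero], collapse = ", ")))
  }
  scale <- ifelse(rs > 0, rs, 1)
  eco_weights(W$w / scale, ids = W$ids, standardized = TRUE)
}

as_eco_weights <- function(W) {
  if (inherits(W, "eco_weights")) W else eco_weights(W)
}

#' Spatial lag of a regional variable
#'
#' Computes `(W x)_i`, the weighted average (for row-standardized `W`) of the
#' variable at region `i`'s neighbours.  With a row-standardized matrix the
#' lag of a constant is that constant; at an isolated region the lag is zero.
#'
#' @param x numeric vector ordered like `W$ids`, or a named vector matched
#'   by id.
#' @param W an [eco_weights] object.
#' @return Numeric vector of spatial lags, named by region id.
#' @export
spatial_lag <- function(x, W) {
  W <- as_eco_weights(W)
  n <- length(W$ids)
  if (!is.null(names(x))) {
    if (!all(W$ids %in% names(x))) {
      abort("names(x) do not cover all regions in W", class = "ecoeff_format_error")
    }
    x <- x[W$ids]
  }
  if (length(x) != n) {
    abort(sprintf("length(x) = %d but W has %d regions", length(x), n),
          class = "ecoeff_format_error")
  }
  drop(W$w %*% x) |> setNames(W$ids)
}

#' Lattice and random contiguity matrices
#'
#' Builds the symmetric binary contiguity structures used by the synthetic
#' panel generator: a ring, a rook-contiguity square lattice, or a random
#' graph in which every node draws `k` neighbours (symmetrized, so degrees
#' are k-ish).  The random scheme resamples until the graph is connected.
#'
#' @param n number of regions.
#' @param scheme `"ring"`, `"rook"`, or `"random-k"`.
#' @param k neighbour count for `"random-k"`.
#' @param seed integer seed for `"random-k"`.
#' @param ids optional region ids (default `R1..Rn`); use e.g.
#'   `sprintf("R%02d", 1:n)` to match [simulate_panel()]'s regions.
#' @return A binary (unstandardized) [eco_weights] object.
#' @export
make_lattice_weights <- function(n, scheme = c("ring", "rook", "random-k"),
                                 k = 3, seed = 1, ids = NULL) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  w <- switch(scheme,
    ring = {
      if (n < 3) abort("ring scheme needs n >= 3", class = "ecoeff_domain_error")
      m <- matrix(0, n, n)
      idx <- seq_len(n)
      m[cbind(idx, idx %% n + 1)] <- 1
      m + t(m)
    },
    rook = {
      side <- round(sqrt(n))
      if (n < 4 || side^2 != n) {
        abort("rook scheme needs n to be a perfect square >= 4",
              class = "ecoeff_domain_error")
      }
      m <- matrix(0, n, n)
      cell <- function(r, c) (r - 1) * side + c
      for (r in seq_len(side)) for (c in seq_len(side)) {
        if (c < side) m[cell(r, c), cell(r, c + 1)] <- 1
        if (r < side) m[cell(r, c), cell(r + 1, c)] <- 1
      }
      m + t(m)
    },
    `random-k` = {
      if (n < k + 1) abort("random-k scheme needs n > k", class = "ecoeff_domain_error")
      withr::with_seed(seed, {
        repeat {
          m <- matrix(0, n, n)
          for (i in seq_len(n)) {
            m[i, sample(setdiff(seq_len(n), i), k)] <- 1
          }
          m <- pmin(m + t(m), 1)
          if (is_connected(m)) break
        }
        m
      })
    })
  eco_weights(w, ids = ids)
}

# breadth-first connectivity check on an adjacency matrix
is_connected <- function(m) {
  n <- nrow(m)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(m[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Read a spatial weight matrix from disk
#'
#' Two plain-text formats are supported: a dense CSV whose header row carries
#' the region ids (an n x n block of nonnegative numbers), and the GAL
#' neighbour-list format.  GAL files are converted to symmetric binary
#' contiguity: an edge is kept if either region lists the other.
#'
#' @param path file path.
#' @param format `"dense-csv"` or `"gal"`; guessed from the extension when
#'   omitted.
#' @return An unstandardized [eco_weights] object.
#' @export
read_weights <- function(path, format = c("auto", "dense-csv", "gal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("weights file not found: %s", path), class = "ecoeff_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.gal$", path, ignore.case = TRUE)) "gal" else "dense-csv"
  }
  if (format == "dense-csv") {
    m <- as.matrix(readr::read_csv(path, show_col_types = FALSE))
    storage.mode(m) <- "double"
    if (nrow(m) != ncol(m)) {
      abort(sprintf("dense weights must be square, got %d x %d", nrow(m), ncol(m)),
            class = "ecoeff_format_error")
    }
    eco_weights(m, ids = colnames(m))
  } else {
    read_gal(path)
  }
}

read_gal <- function(path) {
  lines <- trimws(readLines(path))
  first <- which(nzchar(lines))[1]
  header <- strsplit(lines[[first]], "\\s+")[[1]]
  # GAL headers are either "n" or "0 n <dataset> <key>"
  n <- as.integer(if (length(header) == 1) header[1] else header[2])
  if (is.na(n) || n < 1) {
    abort("cannot parse GAL header", class = "ecoeff_format_error")
  }
  body <- lines[-seq_len(first)]
  ids <- character(n)
  nbrs <- vector("list", n)
  cur <- 1L
  next_nonempty <- function() {
    while (cur <= length(body) && !nzchar(body[[cur]])) cur <<- cur + 1L
    if (cur > length(body)) {
      abort("GAL file ended prematurely", class = "ecoeff_format_error")
    }
    ln <- body[[cur]]
    cur <<- cur + 1L
    ln
  }
  for (i in seq_len(n)) {
    hd <- strsplit(next_nonempty(), "\\s+")[[1]]
    ids[i] <- hd[1]
    k <- as.integer(hd[2])
    nb <- if (k > 0) strsplit(next_nonempty(), "\\s+")[[1]] else character()
    if (length(nb) != k) {
      abort(sprintf("GAL record for '%s' announces %d neighbours but lists %d",
                    ids[i], k, length(nb)), class = "ecoeff_format_error")
    }
    nbrs[[i]] <- nb
  }
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    j <- match(nbrs[[i]], ids)
    if (anyNA(j)) {
      abort(sprintf("GAL neighbour id not in node list: %s",
                    paste(nbrs[[i]][is.na(j)], collapse = ", ")),
            class = "ecoeff_format_error")
    }
    w[i, j] <- 1
  }
  w <- pmax(w, t(w))  # symmetric binary contiguity
  eco_weights(w, ids = ids)
}

#' Write a spatial weight matrix
#'
#' Inverse of [read_weights()]. Dense CSV keeps exact numeric weights; GAL
#' keeps the binary neighbour structure (any positive weight becomes an edge).
#'
#' @param W an [eco_weights] object.
#' @param path destination file.
#' @param format `"dense-csv"` or `"gal"`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, path, format = c("dense-csv", "gal")) {
  format <- match.arg(format)
  W <- as_eco_weights(W)
  if (format == "dense-csv") {
    df <- as.data.frame(W$w)
    names(df) <- W$ids
    readr::write_csv(df, path)
  } else {
    n <- length(W$ids)
    out <- character(1 + 2 * n)
    out[1] <- as.character(n)
    for (i in seq_len(n)) {
      nb <- W$ids[W$w[i, ] > 0]
      out[2 * i] <- paste(W$ids[i], length(nb))
      out[2 * i + 1] <- paste(nb, collapse = " ")
    }
    writeLines(out, path)
  }
  invisible(path)
}
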