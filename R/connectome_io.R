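#' Construct a subject connectome from a count matrix
#'
#' @param counts Square numeric matrix of nonnegative directed streamline
#'   counts (rows = seed ROI, columns = target ROI), dimnames matching the
#'   ROI set.
#' @param roiset A [roiset()] the matrix is aligned to.
#' @param waytotal Per-seed total number of generated streamlines: a single
#'   positive number (recycled), a vector with one entry per ROI, or a named
#'   vector matched by ROI name. May be `NA` if the matrix is already
#'   normalized.
#' @param subject_id,hemisphere Identifying labels.
#' @return An object of class `"subject_connectome"`.
#' @export
subject_connectome <- function(counts, roiset, waytotal = NA_real_,
                               subject_id = NA_character_,
                               hemisphere = NA_character_) {
  counts <- as.matrix(counts)
  n <- nrow(roiset)
  if (nrow(counts) != n || ncol(counts) != n) {
    stop(sprintf("dimension mismatch: matrix is %dx%d but roiset has %d ROIs",
                 nrow(counts), ncol(counts), n))
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative entry at [%s, %s]",
                 roiset$name[neg[1, 1]], roiset$name[neg[1, 2]]))
  }
  dimnames(counts) <- list(roiset$name, roiset$name)
  diag(counts) <- 0  # self-connections are treated as absent
  wt <- waytotal
  if (!is.null(names(wt))) {
    miss <- setdiff(roiset$name, names(wt))
    if (length(miss)) stop("waytotal misses ROI(s): ", paste(miss, collapse = ", "))
    wt <- wt[roiset$name]
  } else {
    wt <- rep_len(as.numeric(wt), n)
    names(wt) <- roiset$name
  }
  structure(
    list(subject_id = subject_id, hemisphere = hemisphere,
         counts = counts, waytotal = wt, roiset = roiset),
    class = "subject_connectome"
  )
}

#' @export
print.subject_connectome <- function(x, ...) {
  cat(sprintf("<subject_connectome> %s (%s): %d ROIs, total count %.4g\n",
              x$subject_id, x$hemisphere, nrow(x$counts), sum(x$counts)))
  invisible(x)
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (!length(line)) stop("empty file: ", path)
  counts <- c(
    "," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
    "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  )
  if (max(counts) > 0) names(counts)[which.max(counts)] else " "
}

#' Read a subject connectivity matrix
#'
#' Reads a CSV/TSV/whitespace-delimited square count matrix. The delimiter
#' is auto-detected. Files may carry ROI labels as a header row plus first
#' column (any ROI order; the matrix is realigned to `roiset`), or be
#' headerless, in which case rows/columns are taken in `roiset` order.
#'
#' @inheritParams subject_connectome
#' @param path Path to the matrix file.
#' @param waytotal As in [subject_connectome()], or the path to a two-column
#'   CSV `name,waytotal`.
#' @return A [subject_connectome()].
#' @export
read_connectivity_matrix <- function(path, roiset, waytotal = NA_real_,
                                     subject_id = NA_character_,
                                     hemisphere = NA_character_) {
  if (!file.exists(path)) stop("connectivity matrix not found: ", path)
  sep <- detect_delim(path)
  raw <- utils::read.table(path, sep = if (sep == " ") "" else sep,
                           header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  first_row <- unlist(raw[1, ], use.names = FALSE)
  has_header <- anyNA(suppressWarnings(as.numeric(first_row[-1])))
  if (has_header) {
    labels_col <- raw[[1]][-1]
    labels_row <- as.character(first_row[-1])
    # tolerate an empty or named corner cell
    body <- raw[-1, -1, drop = FALSE]
    m <- matrix(suppressWarnings(as.numeric(as.matrix(body))),
                nrow = nrow(body), ncol = ncol(body))
    if (anyNA(m)) stop("non-numeric entry in matrix body of ", path)
    unknown <- setdiff(union(labels_col, labels_row), roiset$name)
    if (length(unknown)) {
      stop("unknown ROI label(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    if (length(labels_col) != nrow(roiset) || length(labels_row) != nrow(roiset)) {
      stop(sprintf("dimension mismatch: %s is %dx%d but roiset has %d ROIs",
                   path, length(labels_col), length(labels_row), nrow(roiset)))
    }
    dimnames(m) <- list(labels_col, labels_row)
    m <- m[roiset$name, roiset$name, drop = FALSE]
  } else {
    m <- matrix(suppressWarnings(as.numeric(as.matrix(raw))),
                nrow = nrow(raw), ncol = ncol(raw))
    if (anyNA(m)) stop("non-numeric entry in matrix body of ", path)
    if (nrow(m) != nrow(roiset) || ncol(m) != nrow(roiset)) {
      stop(sprintf("dimension mismatch: %s is %dx%d but roiset has %d ROIs",
                   path, nrow(m), ncol(m), nrow(roiset)))
    }
    dimnames(m) <- list(roiset$name, roiset$name)
  }
  if (is.character(waytotal) && length(waytotal) == 1L) {
    wdt <- data.table::fread(waytotal, header = TRUE, data.table = FALSE)
    if (!all(c("name", "waytotal") %in% names(wdt))) {
      stop("waytotal sidecar needs columns name,waytotal: ", waytotal)
    }
    waytotal <- setNames(as.numeric(wdt$waytotal), wdt$name)
  }
  subject_connectome(m, roiset, waytotal = waytotal,
                     subject_id = subject_id, hemisphere = hemisphere)
}

#' Write a labelled square matrix as CSV
#'
#' Canonical output dialect: comma-separated, ROI labels as header row and
#' first column, corner cell named `roi`.
#'
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @export
write_connectivity_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(roi = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Normalize directed counts by per-seed waytotals
#'
#' Divides every row of the count matrix by that seed's waytotal, mapping
#' counts to connection probabilities in \[0, 1\].
#'
#' @param conn A [subject_connectome()] with positive waytotals.
#' @param clip If `TRUE`, values exceeding 1 after division are clipped to 1
#'   (a warning is emitted either way).
#' @return Directed normalized matrix.
#' @export
normalize_by_waytotal <- function(conn, clip = FALSE) {
  stopifnot(inherits(conn, "subject_connectome"))
  wt <- conn$waytotal
  if (anyNA(wt)) stop("waytotals are missing; supply them or skip normalization")
  if (any(wt <= 0)) {
    stop("waytotal must be positive; offending seed(s): ",
         paste(names(wt)[wt <= 0], collapse = ", "))
  }
  m <- conn$counts / wt  # column vector recycling divides row i by wt[i]
  over <- which(m > 1, arr.ind = TRUE)
  if (nrow(over)) {
    warning(sprintf("%d entr%s exceed the seed waytotal (first: [%s, %s])",
                    nrow(over), if (nrow(over) == 1) "y" else "ies",
                    rownames(m)[over[1, 1]], colnames(m)[over[1, 2]]))
    if (clip) m[m > 1] <- 1
  }
  m
}

#' Symmetrize a directed normalized matrix by directional averaging
#'
#' Each undirected edge weight is the mean of the two directed weights,
#' yielding the weighted-undirected connection probability matrix.
#'
#' @param m Square nonnegative matrix (directed weights).
#' @param roiset Optional [roiset()] carried on the result.
#' @return An object of class `"normalized_connectome"`: a symmetric
#'   weight matrix in \[0, 1\] with zero diagonal, plus a logical mask of
#'   retained ROI pairs (initially all off-diagonal pairs).
#' @export
symmetrize_average <- function(m, roiset = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (any(m < 0)) stop("matrix must be nonnegative")
  w <- (m + t(m)) / 2
  diag(w) <- 0
  mask <- matrix(TRUE, nrow(w), ncol(w), dimnames = dimnames(w))
  diag(mask) <- FALSE
  structure(list(weights = w, mask = mask, roiset = roiset),
            class = "normalized_connectome")
}

#' Restrict a connectome to interlobar (parieto-premotor) pairs
#'
#' Marks all intralobe pairs (parietal–parietal and premotor–premotor) as
#' absent in the retention mask; masked pairs carry no edge (they are not
#' zero-weight edges). Idempotent.
#'
#' @param nc A `"normalized_connectome"`.
#' @param roiset A [roiset()] assigning a lobe to every ROI.
#' @return The connectome with an interlobar-only mask.
#' @export
mask_interlobar <- function(nc, roiset) {
  stopifnot(inherits(nc, "normalized_connectome"))
  if (nrow(nc$weights) != nrow(roiset)) {
    stop("roiset does not match connectome dimension")
  }
  inter <- outer(roiset$lobe, roiset$lobe, FUN = "!=")
  dimnames(inter) <- dimnames(nc$weights)
  nc$mask <- nc$mask & inter
  nc$roiset <- roiset
  nc
}

#' Count the retained ROI pairs of a connectome mask
#'
#' @param nc A `"normalized_connectome"`.
#' @return Number of unordered retained pairs.
#' @export
n_retained_pairs <- function(nc) {
  stopifnot(inherits(nc, "normalized_connectome"))
  sum(nc$mask) / 2
}

#' @export
print.normalized_connectome <- function(x, ...) {
  cat(sprintf("<normalized_connectome> %d ROIs, %d retained pairs, max weight %.4g\n",
              nrow(x$weights), n_retained_pairs(x), max(x$weights)))
  invisible(x)
}
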