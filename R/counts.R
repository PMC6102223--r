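#' Size of the UMI space
#'
#' Number of distinct unique molecular identifiers encodable by a random
#' barcode: `alphabet_size ^ barcode_length` (4096 for the 6-bp UMIs of
#' CEL-Seq2/SORT-Seq libraries).
#'
#' @param barcode_length Barcode length in bases (>= 0).
#' @param alphabet_size Alphabet size (default 4).
#' @return Number of possible UMIs.
#' @export
umi_space_size <- function(barcode_length, alphabet_size = 4) {
  barcode_length <- .check_count(barcode_length, "barcode_length")
  .check_number(alphabet_size, "alphabet_size", lower = 1)
  alphabet_size^barcode_length
}

#' Correct distinct-UMI counts for barcode collisions
#'
#' With `m` molecules labelled uniformly at random from `K` possible UMIs,
#' the expected number of distinct UMIs observed is
#' `E[k] = K (1 - exp(-m/K))` under Poissonian counting statistics.
#' Inverting gives the expected molecule count for an observed distinct
#' count `k`: `m = -K ln(1 - k/K)`. The correction is >= k, increasing and
#' convex in k. A `"binomial"` variant using the exact finite-pool
#' occupancy, `m = ln(1 - k/K) / ln(1 - 1/K)`, is available; the two
#' differ by < 0.02% at K = 4096.
#'
#' Corrected counts are returned as reals; if integers are needed, round
#' half-to-even at export time only ([round()]), to avoid biasing
#' downstream sums.
#'
#' @param k Observed distinct-UMI counts (vectorised), `0 <= k < K`.
#' @param umi_space UMI-space size K (default 4096).
#' @param method `"poisson"` (default) or `"binomial"`.
#' @return Expected molecule counts (real, same length as `k`).
#' @export
correct_umi_count <- function(k, umi_space = 4096,
                              method = c("poisson", "binomial")) {
  method <- match.arg(method)
  .check_number(umi_space, "umi_space", lower = 1, allow_lower = FALSE)
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0))
    .stopf("'k' must be nonnegative and finite")
  if (any(k >= umi_space))
    .stopf("observed distinct-UMI count saturates the UMI space (k >= K); clamp to K - 1 explicitly if that is intended")
  if (method == "poisson") -umi_space * log1p(-k / umi_space)
  else log1p(-k / umi_space) / log1p(-1 / umi_space)
}

#' Collision-correct a whole gene x cell matrix
#'
#' Applies [correct_umi_count()] entry-wise.
#'
#' @param counts Gene x cell matrix of observed distinct-UMI counts.
#' @param umi_space UMI-space size K.
#' @param method Passed to [correct_umi_count()].
#' @return Real-valued matrix of expected molecule counts.
#' @export
correct_umi_matrix <- function(counts, umi_space = 4096,
                               method = c("poisson", "binomial")) {
  if (!is.matrix(counts)) .stopf("'counts' must be a matrix")
  out <- correct_umi_count(as.vector(counts), umi_space, method)
  matrix(out, nrow = nrow(counts), dimnames = dimnames(counts))
}

#' Filter cells by total transcript count
#'
#' Retains exactly the cells (columns) whose totals reach `min_total`;
#' cells below the minimum cannot be down-sampled to it and are dropped.
#'
#' @param counts Gene x cell count matrix.
#' @param min_total Minimum column total (default 1700, the down-sampling
#'   target of the SORT-Seq processing path).
#' @return A list with `counts` (the retained columns) and `dropped`, a
#'   data frame of dropped cell ids and their totals.
#' @export
filter_cells <- function(counts, min_total = 1700) {
  if (!is.matrix(counts)) .stopf("'counts' must be a matrix")
  min_total <- .check_count(min_total, "min_total")
  totals <- colSums(counts)
  ids <- colnames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(counts)))
  keep <- totals >= min_total
  list(counts = counts[, keep, drop = FALSE],
       dropped = data.frame(cell_id = ids[!keep],
                            total = unname(totals[!keep])))
}

#' Down-sample one cell to a fixed transcript total
#'
#' Draws `target` transcripts without replacement from the cell's pool
#' (multivariate hypergeometric, realised as sequential conditional
#' [stats::rhyper()] draws), so the result sums to `target` exactly and
#' preserves per-gene proportions in expectation.
#'
#' @param x Nonnegative integer counts of one cell (a column).
#' @param target Target total, `0 <= target <= sum(x)`.
#' @param seed Optional integer seed.
#' @return Integer vector summing to `target`.
#' @export
downsample_cell <- function(x, target, seed = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != as.integer(x)))
    .stopf("'x' must be nonnegative integers")
  target <- .check_count(target, "target")
  total <- sum(x)
  if (total < target)
    .stopf("cell total (%d) is below the target (%d); filter cells first",
           total, target)
  .set_seed(seed)
  out <- integer(length(x))
  m <- target
  remaining <- total
  for (i in which(x > 0L)) {
    if (m == 0L) break
    xi <- x[i]
    if (remaining == xi) {
      out[i] <- m
      m <- 0L
      break
    }
    d <- stats::rhyper(1, xi, remaining - xi, m)
    out[i] <- d
    m <- m - d
    remaining <- remaining - xi
  }
  out
}

#' Down-sample every cell of a matrix to a common total
#'
#' @param counts Gene x cell count matrix; every column total must be
#'   >= `target` (use [filter_cells()] first).
#' @param target Common per-cell total (default 1700).
#' @param seed Optional integer seed.
#' @return Integer matrix with every column summing to `target`.
#' @export
downsample_matrix <- function(counts, target = 1700, seed = NULL) {
  if (!is.matrix(counts)) .stopf("'counts' must be a matrix")
  target <- .check_count(target, "target")
  if (any(colSums(counts) < target))
    .stopf("some cells total below the target; filter cells first")
  .set_seed(seed)
  out <- vapply(seq_len(ncol(counts)),
                function(j) downsample_cell(counts[, j], target),
                integer(nrow(counts)))
  dimnames(out) <- dimnames(counts)
  out
}

#' Depth-normalize a count matrix by filtering and down-sampling
#'
#' The SORT-Seq normalization path: drop cells whose totals fall below
#' `min_total`, then down-sample each retained cell to exactly
#' `min_total` transcripts.
#'
#' @param counts Gene x cell count matrix.
#' @param min_total Minimum and target per-cell total (default 1700).
#' @param seed Optional integer seed.
#' @return A list with `counts` (every column total equals `min_total`)
#'   and `dropped` (as in [filter_cells()]).
#' @export
normalize_counts <- function(counts, min_total = 1700, seed = NULL) {
  flt <- filter_cells(counts, min_total)
  .set_seed(seed)
  flt$counts <- downsample_matrix(flt$counts, min_total)
  flt
}

#' Read and write gene x cell matrices in MatrixMarket format
#'
#' `write_count_mtx()` writes `<prefix>.mtx` together with the label
#' sidecars `<prefix>.genes.tsv` and `<prefix>.cells.tsv`;
#' `read_count_mtx()` reads them back into a dense integer matrix with
#' dimnames.
#'
#' @param counts Gene x cell matrix with dimnames.
#' @param dir Directory for the three files (created if needed).
#' @param prefix File-name prefix (default `"counts"`).
#' @return `write_count_mtx()` returns the `.mtx` path invisibly;
#'   `read_count_mtx()` returns the matrix.
#' @export
write_count_mtx <- function(counts, dir, prefix = "counts") {
  if (!is.matrix(counts)) .stopf("'counts' must be a matrix")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  genes <- rownames(counts)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(counts)))
  cells <- colnames(counts)
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(counts)))
  writeLines(genes, file.path(dir, paste0(prefix, ".genes.tsv")))
  writeLines(cells, file.path(dir, paste0(prefix, ".cells.tsv")))
  invisible(path)
}

#' @rdname write_count_mtx
#' @export
read_count_mtx <- function(dir, prefix = "counts") {
  path <- file.path(dir, paste0(prefix, ".mtx"))
  if (!file.exists(path)) .stopf("no such file: %s", path)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(file.path(dir, paste0(prefix, ".genes.tsv")))
  colnames(m) <- readLines(file.path(dir, paste0(prefix, ".cells.tsv")))
  storage.mode(m) <- "integer"
  m
}
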