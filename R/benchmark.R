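#' Operation-count scaling benchmark for the matrix-free product
#'
#' For each cell of an (n_samples x sequence_length) grid, simulates `reps`
#' tree sequences, runs the instrumented branch-GRM-vector product with a
#' random weight vector, and aggregates the per-transition node-touch
#' counters.  Operation counts — not wall-clock — are the asserted quantity,
#' since they are machine-independent; elapsed time is reported for
#' information only.
#'
#' @param n_values vector of sample sizes.
#' @param L_values vector of sequence lengths (recycled against `n_values`'s
#'   grid).
#' @param reps replicate simulations per cell.
#' @param seed RNG seed; replicate r of cell i uses a seed derived from it.
#' @param N_e,recomb_rate simulation parameters passed to
#'   [simulate_coalescent_ts()].
#' @return A `benchmark_report`: data.frame with one row per cell, columns
#'   `n`, `L`, `reps`, `mean_nodes_per_transition` (and min/max over
#'   replicates), `mean_transitions`, `mean_seconds`.
#' @export
run_benchmark <- function(n_values, L_values = 1e5, reps = 3L, seed = 1L,
                          N_e = 1e4, recomb_rate = 1e-8) {
  grid <- expand.grid(n = n_values, L = L_values)
  if (nrow(grid) == 0L) stop("benchmark grid is empty")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; L <- grid$L[i]
    vals <- numeric(0); trans <- numeric(0); secs <- numeric(0)
    for (r in seq_len(reps)) {
      res <- tryCatch({
        ts <- simulate_coalescent_ts(n, L, N_e = N_e,
                                     recomb_rate = recomb_rate,
                                     seed = derive_seed(seed, paste(i, r)))
        w <- with_seed(derive_seed(seed, paste("w", i, r)),
                       stats::rnorm(n_samples(ts)))
        t0 <- proc.time()[["elapsed"]]
        im <- instrument_matvec(ts, w)
        list(nodes = im$mean_nodes_per_transition,
             ntrans = nrow(im$counters) - 2L,
             sec = proc.time()[["elapsed"]] - t0)
      }, error = function(e) {
        warning(sprintf("benchmark cell n=%d L=%g rep %d failed: %s",
                        n, L, r, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        vals <- c(vals, res$nodes)
        trans <- c(trans, res$ntrans)
        secs <- c(secs, res$sec)
      }
    }
    rows[[i]] <- data.frame(
      n = n, L = L, reps = length(vals),
      mean_nodes_per_transition = mean(vals),
      min_nodes_per_transition = suppressWarnings(min(vals)),
      max_nodes_per_transition = suppressWarnings(max(vals)),
      mean_transitions = mean(trans),
      mean_seconds = mean(secs))
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("benchmark_report", class(out))
  out
}

#' Serialize / load a benchmark report
#' @param report a `benchmark_report`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_benchmark_report` returns the report.
#' @export
write_benchmark_report <- function(report, path) {
  jsonlite::write_json(list(seed = attr(report, "seed"),
                            cells = as.data.frame(unclass(report))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_benchmark_report
#' @export
read_benchmark_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.data.frame(obj$cells)
  attr(out, "seed") <- obj$seed
  class(out) <- c("benchmark_report", class(out))
  out
}
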