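#' Benchmark parameter sweep: generate, detect, evaluate
#'
#' Replicates the benchmark experimental design: for every combination of
#' `muA`, `muB` and `p`, generate `replicates` labeled benchmark 2-HNs
#' (replicate seeds are `base_seed + replicate - 1` plus a grid offset),
#' run the detector on each, and score the found partition against the
#' planted labels.
#'
#' @param muA,muB,p numeric vectors defining the grid.
#' @param replicates networks per grid cell.
#' @param base_spec a [benchmark_spec()] supplying all other parameters.
#' @param base_seed integer; all randomness derives from it.
#' @param detect_cfg a [detect_config()]; its seed is re-derived per run.
#' @return data.frame with one row per run: grid values, `replicate`,
#'   `seed`, `nmi`, `ca`, `n_modules`, `n_mixed`, `mQ`, and an `error`
#'   column (NA on success; generation failures are recorded, not fatal).
#' @export
run_sweep <- function(muA = 0.2, muB = 0.2, p = 0.5, replicates = 10,
                      base_spec = benchmark_spec(), base_seed = 1L,
                      detect_cfg = detect_config()) {
  grid <- expand.grid(muA = muA, muB = muB, p = p,
                      replicate = seq_len(replicates))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    seed <- as.integer((base_seed + 7907L * (i - 1L)) %% 2147483647)
    row <- data.frame(g, seed = seed, nmi = NA_real_, ca = NA_real_,
                      n_modules = NA_integer_, n_mixed = NA_integer_,
                      mQ = NA_real_, error = NA_character_)
    res <- tryCatch({
      spec <- base_spec
      spec$muA <- g$muA; spec$muB <- g$muB; spec$p <- g$p
      spec$seed <- seed
      if (spec$weighting == "GPi") spec$muW <- 1 - g$p
      else if (spec$weighting == "GA") spec$muW <- g$muA
      else if (spec$weighting == "GB") spec$muW <- g$muB
      bench <- generate_benchmark(spec)
      cfg <- detect_cfg
      cfg$seed <- seed
      det <- mixmod_detect(bench$net, cfg)
      ev <- evaluate_partition(bench$labels, det$partition, bench$net)
      row$nmi <- ev$nmi; row$ca <- ev$ca
      row$n_modules <- det$n_modules; row$n_mixed <- det$n_mixed_modules
      row$mQ <- det$mQ
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell summary of a sweep table
#'
#' @param sweep output of [run_sweep()].
#' @return data.frame with one row per (muA, muB, p) cell: replicate count,
#'   mean and sd of NMI and CA.
#' @export
summarize_sweep <- function(sweep) {
  ok <- sweep[is.na(sweep$error), ]
  key <- interaction(ok$muA, ok$muB, ok$p, drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  idx <- match(levels(key), as.character(key))
  data.frame(muA = ok$muA[idx], muB = ok$muB[idx], p = ok$p[idx],
             n = as.integer(table(key)[levels(key)]),
             mean_nmi = agg(ok$nmi, mean), sd_nmi = agg(ok$nmi, stats::sd),
             mean_ca = agg(ok$ca, mean), sd_ca = agg(ok$ca, stats::sd))
}
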