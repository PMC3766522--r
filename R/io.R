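#' Read a trace from delimited text
#'
#' Accepts either a one-column file of samples (with the sampling interval
#' given by a `# dt <seconds>` header line or the `dt` argument), or a
#' two-column file of `time value` pairs, from which `dt` is inferred and
#' validated for uniform spacing (relative tolerance `1e-9`); non-uniform
#' input is an error, never resampled.
#'
#' @param path file path.
#' @param dt sampling interval in seconds; overrides/replaces a header.
#' @return A [shot_noise_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 5L)
  hdr <- grep("^#", head_lines, value = TRUE)
  if (is.null(dt) && length(hdr)) {
    m <- regmatches(hdr, regexec("dt[[:space:]=]+([0-9.eE+-]+)", hdr))
    vals <- vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_,
                   "")
    vals <- vals[!is.na(vals)]
    if (length(vals)) dt <- as.numeric(vals[1])
  }
  dat <- utils::read.table(path, comment.char = "#",
                           colClasses = "numeric")
  if (ncol(dat) == 1L) {
    if (is.null(dt))
      stop("one-column trace needs 'dt' (argument or '# dt' header)")
    samples <- dat[[1]]
  } else if (ncol(dat) == 2L) {
    t <- dat[[1]]
    samples <- dat[[2]]
    if (length(t) < 2L) stop("two-column trace needs at least 2 rows")
    steps <- diff(t)
    dt_obs <- stats::median(steps)
    if (any(abs(steps - dt_obs) > 1e-9 * dt_obs))
      stop("non-uniform sampling in ", path,
           " (relative tolerance 1e-9); refusing to resample")
    if (!is.null(dt) && abs(dt - dt_obs) > 1e-9 * dt_obs)
      stop("supplied dt disagrees with the time column")
    dt <- dt_obs
  } else {
    stop("trace file must have one or two numeric columns")
  }
  if (anyNA(samples)) stop("non-numeric content in ", path)
  shot_noise_trace(samples, dt)
}

#' Write a trace as delimited text
#'
#' One sample per row with a `# dt <seconds>` header, printed with 17
#' significant digits so that [read_trace()] recovers the samples exactly.
#'
#' @param trace a [shot_noise_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cubicm_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt %.17g", trace$dt), con)
  writeLines(sprintf("%.17g", trace$samples), con)
  invisible(path)
}

#' Write a raster as two-column delimited text
#'
#' @param raster a `data.frame` with columns `neuron` and `time`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster[, c("neuron", "time")], path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

# plain-list view of a result, used for JSON reports
result_to_list <- function(res) {
  stopifnot(inherits(res, "cubicm_result"))
  list(
    xi_hat = res$xi_hat,
    censored = res$censored,
    alpha = res$alpha,
    f_c = res$f_c,
    correction = res$correction,
    k1 = res$cumulants$k1,
    k2 = res$cumulants$k2,
    k3 = res$cumulants$k3,
    L = res$L,
    dt = res$dt,
    resting = res$resting,
    kernel = res$kernel[!vapply(res$kernel, is.null, TRUE)],
    seed = res$seed,
    tests = res$tests
  )
}

#' Write an inference result as a JSON report
#'
#' Serializes the settings, sample cumulants, correction factor, per-order
#' test table (`kappa3_star`, `sigma_star`, `p`) and the inferred bound.
#' Reports contain no timestamps, so identical runs give byte-identical
#' files.
#'
#' @param result a `"cubicm_result"` from [cubicm()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(result_to_list(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rerun the simulation studies behind the method's validation figures
#'
#' Executes one of the named simulation studies, writes per-run JSON
#' records and a CSV summary table, and returns the summary.  `scale`
#' multiplies the repetition counts (durations and population parameters
#' are fixed by the study design).
#'
#' Available studies:
#' * `fig3_typeI`: type-I error of the order-1 test, with and without the
#'   correlated-samples correction (200 independent neurons at 10
#'   spikes/s, exponential tau = 10 ms, 50 s, 20 kHz, 200 repetitions).
#' * `fig4_sensitivity`: mean inferred order for the two default
#'   correlated data sets (orders 20 and 40).
#' * `fig5_jitter`: mean inferred order under uniform spike-time jitter.
#' * `fig6_nonpoisson`: inferred-order ratio for lognormal-ISI versus
#'   Poisson populations with a matched (binomial) correlation structure.
#' * `fig7_robustness`: directional effects of a wrong resting offset,
#'   wrong assumed amplitude, heterogeneous amplitudes and added
#'   inhibition.
#'
#' @param experiment one of the ids above.
#' @param scale repetition-count multiplier (default 1).
#' @param duration_scale multiplier on the simulated durations; 1 is the
#'   study design, smaller values give quick smoke runs.
#' @param seed integer seed for the whole study.
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return The summary `data.frame`, invisibly when files are written.
#' @export
run_reproduction <- function(experiment, scale = 1, seed = 1,
                             out_dir = NULL, duration_scale = 1) {
  experiments <- c("fig3_typeI", "fig4_sensitivity", "fig5_jitter",
                   "fig6_nonpoisson", "fig7_robustness")
  if (!experiment %in% experiments)
    stop("unknown experiment id; use one of: ",
         paste(experiments, collapse = ", "))
  set.seed(seed)
  runner <- switch(experiment,
                   fig3_typeI = repro_fig3,
                   fig4_sensitivity = repro_fig4,
                   fig5_jitter = repro_fig5,
                   fig6_nonpoisson = repro_fig6,
                   fig7_robustness = repro_fig7)
  out <- runner(scale, duration_scale)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(c(list(experiment = experiment, seed = seed,
                                scale = scale), out["runs"]),
                         file.path(out_dir, paste0(experiment, "_runs.json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$summary,
                     file.path(out_dir, paste0(experiment, "_summary.csv")),
                     row.names = FALSE)
    return(invisible(out$summary))
  }
  out$summary
}

# shared machinery: simulate an independent-Poisson shot-noise trace
sim_poisson_trace <- function(rate, kernel, T, dt, warmup = 1) {
  n_tot <- as.integer(round((T + warmup) / dt))
  cnt <- stats::rpois(n_tot, rate * dt)
  filter_counts(cnt, kernel, warmup = warmup, dt = dt)
}

# simulate a CPP structure and filter it
sim_structure_trace <- function(structure, kernel, T, dt, warmup = 1) {
  z <- simulate_cpp(structure, T + warmup, dt)
  filter_counts(z, kernel, warmup = warmup)
}

repro_fig3 <- function(scale, dscale = 1) {
  reps <- max(1L, as.integer(round(200 * scale)))
  ker <- exp_kernel(1, 0.010)
  dt <- 5e-5
  runs <- vector("list", reps)
  rej_un <- rej_co <- logical(reps)
  for (i in seq_len(reps)) {
    tr <- sim_poisson_trace(200 * 10, ker, T = 50 * dscale, dt = dt)
    un <- cubicm(tr, ker, correction = FALSE, k_max = 1)
    co <- cubicm(tr, ker, correction = TRUE, k_max = 1)
    rej_un[i] <- un$p_values[1] <= un$alpha
    rej_co[i] <- co$p_values[1] <= co$alpha
    runs[[i]] <- list(run = i, p_uncorrected = un$p_values[1],
                      p_corrected = co$p_values[1], f_c = co$f_c)
  }
  list(summary = data.frame(
         repetitions = reps,
         rejection_uncorrected = mean(rej_un),
         rejection_corrected = mean(rej_co)),
       runs = runs)
}

fig4_datasets <- function() {
  list(
    blue = list(spec = population_spec(N = 1000, N_c = 100, c = 0.05,
                                       order = 20, rate = 5),
                kernel = exp_kernel(1, 0.020), T = 60, reps = 50),
    green = list(spec = population_spec(N = 10000, N_c = 200, c = 0.02,
                                        order = 40, rate = 2),
                 kernel = exp_kernel(1, 0.005), T = 100, reps = 20))
}

repro_fig4 <- function(scale, dscale = 1) {
  dt <- 5e-5
  runs <- list()
  summary <- NULL
  for (nm in names(fig4_datasets())) {
    ds <- fig4_datasets()[[nm]]
    reps <- max(1L, as.integer(round(ds$reps * scale)))
    st <- build_structure(ds$spec)
    xi <- integer(reps)
    for (i in seq_len(reps)) {
      tr <- sim_structure_trace(st, ds$kernel, ds$T * dscale, dt)
      res <- cubicm(tr, ds$kernel)
      xi[i] <- res$xi_hat
      runs[[length(runs) + 1L]] <-
        list(dataset = nm, run = i, xi_hat = res$xi_hat, f_c = res$f_c)
    }
    summary <- rbind(summary, data.frame(
      dataset = nm, repetitions = reps, true_order = ds$spec$order,
      mean_xi = mean(xi), sd_xi = stats::sd(xi)))
  }
  list(summary = summary, runs = runs)
}

repro_fig5 <- function(scale, dscale = 1) {
  reps <- max(1L, as.integer(round(10 * scale)))
  dt <- 5e-5
  spec <- population_spec(N = 1000, N_c = 100, c = 0.05, order = 20,
                          rate = 5)
  ker <- exp_kernel(1, 0.002)
  T <- 20 * dscale
  jit <- c(0, 5e-4, 1e-3, 2.5e-3, 5e-3)
  runs <- list()
  summary <- NULL
  for (j in jit) {
    xi <- integer(reps)
    for (i in seq_len(reps)) {
      ras <- simulate_raster(spec, T + 1)
      ras <- apply_jitter(ras, j, t_max = T + 1)
      z <- bin_raster(ras, T + 1, dt)
      tr <- filter_counts(z, ker, warmup = 1)
      res <- cubicm(tr, ker)
      xi[i] <- res$xi_hat
      runs[[length(runs) + 1L]] <- list(jitter = j, run = i,
                                        xi_hat = res$xi_hat)
    }
    summary <- rbind(summary, data.frame(
      jitter = j, repetitions = reps, mean_xi = mean(xi),
      sd_xi = stats::sd(xi)))
  }
  list(summary = summary, runs = runs)
}

repro_fig6 <- function(scale, dscale = 1) {
  reps <- max(1L, as.integer(round(5 * scale)))
  dt <- 5e-5
  T <- 100 * dscale
  spec <- population_spec(N = 200, N_c = 200, c = 0.01, rate = 10,
                          isi_cv = 1)
  st <- build_structure_binomial(200, 200, 0.01, 10)
  cvs <- c(0.5, 1, 2)
  taus <- c(0.001, 0.010, 0.050)
  runs <- list()
  summary <- NULL
  for (tau in taus) {
    ker <- exp_kernel(1, tau)
    for (cv in cvs) {
      ratio <- numeric(reps)
      for (i in seq_len(reps)) {
        tr_pp <- sim_structure_trace(st, ker, T, dt)
        sp <- spec; sp$isi_cv <- cv
        z_np <- simulate_nonpoisson(sp, T + 1, dt, structure = "binomial")
        tr_np <- filter_counts(z_np, ker, warmup = 1)
        xi_pp <- cubicm(tr_pp, ker)$xi_hat
        xi_np <- cubicm(tr_np, ker)$xi_hat
        ratio[i] <- xi_np / xi_pp
        runs[[length(runs) + 1L]] <- list(tau = tau, cv = cv, run = i,
                                          xi_pp = xi_pp, xi_np = xi_np)
      }
      summary <- rbind(summary, data.frame(
        tau = tau, isi_cv = cv, repetitions = reps,
        mean_ratio = mean(ratio), sd_ratio = stats::sd(ratio)))
    }
  }
  list(summary = summary, runs = runs)
}

repro_fig7 <- function(scale, dscale = 1) {
  reps <- max(1L, as.integer(round(10 * scale)))
  dt <- 5e-5
  T <- 100 * dscale
  N <- 200
  ker <- exp_kernel(1, 0.010)
  st <- build_structure_binomial(N, N, 0.01, 10)
  grids <- list(
    resting_shift = c(-0.5, 0, 0.5),       # units of A
    amplitude_ratio = c(0.5, 1, 2),        # assumed / true A
    amplitude_cv = c(0, 1, 2),
    inhibition_ratio = c(0, 0.4, 0.8))     # lambda_I / lambda_E (< 1, so
                                           # the net mean rate stays positive)
  runs <- list()
  summary <- NULL
  for (i in seq_len(reps)) {
    tr <- sim_structure_trace(st, ker, T, dt)
    for (s in grids$resting_shift) {
      xi <- cubicm(tr, ker, resting = s)$xi_hat
      runs[[length(runs) + 1L]] <- list(variant = "resting_shift",
                                        value = s, run = i, xi_hat = xi)
    }
    for (r in grids$amplitude_ratio) {
      kr <- exp_kernel(r, 0.010)
      xi <- cubicm(tr, kr)$xi_hat
      runs[[length(runs) + 1L]] <- list(variant = "amplitude_ratio",
                                        value = r, run = i, xi_hat = xi)
    }
    for (rr in grids$inhibition_ratio) {
      sp <- population_spec(N = N, rate = 10, inhib_rate = 10 * rr)
      trm <- mix_inhibition(tr, sp, ker)
      xi <- cubicm(trm, ker)$xi_hat
      runs[[length(runs) + 1L]] <- list(variant = "inhibition_ratio",
                                        value = rr, run = i, xi_hat = xi)
    }
    for (cv in grids$amplitude_cv) {
      ras <- simulate_raster_binomial(N, 0.01, 10, T + 1)
      trh <- heterogeneous_amplitude_filter(ras, N, ker, cv, T + 1, dt)
      xi <- cubicm(trh, ker)$xi_hat
      runs[[length(runs) + 1L]] <- list(variant = "amplitude_cv",
                                        value = cv, run = i, xi_hat = xi)
    }
  }
  df <- do.call(rbind, lapply(runs, as.data.frame))
  summary <- do.call(rbind, lapply(split(df, list(df$variant, df$value),
                                         drop = TRUE), function(g) {
    data.frame(variant = g$variant[1], value = g$value[1],
               repetitions = nrow(g), mean_xi = mean(g$xi_hat),
               sd_xi = stats::sd(g$xi_hat))
  }))
  rownames(summary) <- NULL
  list(summary = summary, runs = runs)
}

# raster for a binomial (MIP-style) correlated pool: every spike of a
# carrier Poisson process at rate/c is copied into each neuron with
# probability c
simulate_raster_binomial <- function(N, c, rate, T) {
  m <- stats::rpois(1L, rate / c * T)
  if (m == 0L) return(data.frame(neuron = integer(0), time = numeric(0)))
  ev_t <- stats::runif(m, 0, T)
  sizes <- stats::rbinom(m, N, c)
  keep <- sizes > 0L
  ev_t <- ev_t[keep]; sizes <- sizes[keep]
  neuron <- unlist(lapply(sizes, function(s) sample.int(N, s)))
  data.frame(neuron = as.integer(neuron),
             time = rep(ev_t, times = sizes))
}
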