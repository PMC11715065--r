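#' Prediction correction of an observation
#'
#' Rescales an observation by the ratio of the bin's median population
#' prediction to the record's own population prediction,
#' `y * pred_bin / pred_ij`, so records with different doses or weights
#' become comparable within a time bin.
#'
#' @param y Observed value(s).
#' @param pred_ij Population prediction for the record(s); must be `> 0`
#'   (zero predictions yield `NA` with a warning, and such records are
#'   excluded from VPC summaries).
#' @param pred_bin Median population prediction in the record's bin.
#'
#' @return Corrected observation(s).
#' @export
#' @examples
#' prediction_correct(10, 5, 6)  # 12
prediction_correct <- function(y, pred_ij, pred_bin) {
  out <- y * pred_bin / pred_ij
  if (any(pred_ij <= 0)) {
    warning("prediction_correct: record(s) with non-positive population ",
            "prediction excluded", call. = FALSE)
    out[pred_ij <= 0] <- NA_real_
  }
  out
}

#' Coerce to a population model
#'
#' @param x A `population_model` (returned unchanged) or a `fit_result`,
#'   whose estimated fixed effects, BSV variances and residual components
#'   are assembled into a generative model.
#' @return A [population_model()].
#' @export
as_population <- function(x) UseMethod("as_population")

#' @export
as_population.population_model <- function(x) x

#' @export
as_population.fit_result <- function(x) {
  th <- x$theta
  population_model(
    pk = pk_parameters(th[["CL"]], th[["Q"]], th[["V1"]], th[["V2"]],
                       th[["t_half_keo"]]),
    pd = pd_parameters(th[["E0"]], th[["Emax"]], th[["Ce50"]], th[["N"]]),
    ida = ida_parameters(th[["K_IDA"]], th[["DUR_IDA"]], th[["SLOPE_IDA"]]),
    omega = x$omega, sigma = x$sigma)
}

# nominal-time binning with small bins merged into their neighbour
.vpc_bins <- function(times, min_bin) {
  tab <- table(times)
  bins <- as.numeric(names(tab))
  counts <- as.integer(tab)
  assign_to <- seq_along(bins)
  merged <- FALSE
  i <- 1L
  while (i <= length(bins)) {
    idx <- which(assign_to == i)
    if (length(idx) && sum(counts[idx]) < min_bin && length(unique(assign_to)) > 1L) {
      target <- if (i < max(assign_to)) min(assign_to[assign_to > i]) else
        max(assign_to[assign_to < i])
      assign_to[idx] <- target
      merged <- TRUE
      i <- 1L  # restart; bin sizes changed
    } else i <- i + 1L
  }
  key <- match(assign_to, sort(unique(assign_to)))
  list(bin_of_time = stats::setNames(key, bins), merged = merged)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates replicate cohorts from a fitted (or given) population model at
#' the observed design and compares the 10th/50th/90th percentiles of the
#' prediction-corrected observations with the simulated percentile bands
#' and their 95% confidence intervals, per nominal-time bin and
#' observation channel.
#'
#' @param dataset The observed `study_dataset`.
#' @param fit A `fit_result` or a [population_model()] to simulate from.
#' @param n_replicates Number of simulated cohorts (`>= 100`).
#' @param seed Integer seed; results are deterministic given it.
#' @param channels Channels to check (`"conc"`, `"r"`).
#' @param probs Percentiles summarised (default 10/50/90).
#' @param min_bin Bins with fewer observations are merged into a
#'   neighbouring bin (and the result flagged).
#'
#' @return A `vpc_result`: list with `bins` (one row per channel x bin x
#'   percentile: observed value, simulated median and 95% CI),
#'   `n_replicates`, and `merged_bins` flag.
#' @export
run_vpc <- function(dataset, fit, n_replicates = 500, seed = 1,
                    channels = c("conc", "r"), probs = c(0.1, 0.5, 0.9),
                    min_bin = 3) {
  if (n_replicates < 100)
    stop("run_vpc: 'n_replicates' must be at least 100", call. = FALSE)
  pop <- as_population(fit)
  channels <- match.arg(channels, c("conc", "r"), several.ok = TRUE)
  blocks <- .prepare_blocks(dataset, channels)
  theta <- unlist(theta_vector(pop))[.par_names]

  # typical-subject (population) predictions per record
  pred_pop <- lapply(blocks, function(b)
    .block_predict_p(theta * b$wfac, b))

  set.seed(seed)
  eta_names <- names(pop$omega)
  eta_idx <- match(eta_names, .par_names)
  sim_once <- function() {
    lapply(blocks, function(b) {
      ef <- numeric(length(.par_names))
      if (length(eta_idx))
        ef[eta_idx] <- stats::rnorm(length(eta_idx), 0, sqrt(pop$omega))
      f <- .block_predict_p(.indiv_p(theta, b$wfac, ef), b)
      sp <- ifelse(b$is_conc, pop$sigma[["conc_prop"]], pop$sigma[["r_prop"]])
      sa <- ifelse(b$is_conc, pop$sigma[["conc_add"]], pop$sigma[["r_add"]])
      pmax(f * (1 + stats::rnorm(length(f), 0, sp)) +
             stats::rnorm(length(f), 0, sa), 0)
    })
  }

  out <- list()
  merged_any <- FALSE
  for (ch in channels) {
    dvid <- if (ch == "conc") 1L else 2L
    tt <- unlist(lapply(blocks, function(b) b$obs$TIME[b$obs$DVID == dvid]))
    yy <- unlist(lapply(blocks, function(b) b$obs$DV[b$obs$DVID == dvid]))
    pp <- unlist(lapply(seq_along(blocks), function(i)
      pred_pop[[i]][blocks[[i]]$obs$DVID == dvid]))
    if (!length(tt)) next
    bn <- .vpc_bins(tt, min_bin)
    merged_any <- merged_any || bn$merged
    bin_id <- bn$bin_of_time[as.character(tt)]
    pred_bin <- tapply(pp, bin_id, stats::median)[as.character(bin_id)]
    pc_obs <- prediction_correct(yy, pp, pred_bin)

    n_bins <- length(unique(bin_id))
    obs_q <- t(vapply(sort(unique(bin_id)), function(bid)
      stats::quantile(pc_obs[bin_id == bid], probs, na.rm = TRUE,
                      names = FALSE),
      numeric(length(probs))))
    sim_q <- array(NA_real_, c(n_replicates, n_bins, length(probs)))
    for (r in seq_len(n_replicates)) {
      ys <- sim_once()
      ysv <- unlist(lapply(seq_along(blocks), function(i)
        ys[[i]][blocks[[i]]$obs$DVID == dvid]))
      pc_sim <- prediction_correct(ysv, pp, pred_bin)
      sim_q[r, , ] <- t(vapply(sort(unique(bin_id)), function(bid)
        stats::quantile(pc_sim[bin_id == bid], probs, na.rm = TRUE,
                        names = FALSE),
        numeric(length(probs))))
    }
    for (k in seq_along(probs)) {
      bins_k <- data.frame(
        channel = ch,
        time = vapply(sort(unique(bin_id)), function(bid)
          stats::median(tt[bin_id == bid]), numeric(1)),
        n = as.integer(table(bin_id)),
        percentile = probs[k],
        observed = obs_q[, k],
        sim_median = apply(sim_q[, , k, drop = FALSE], 2, stats::median),
        sim_lower = apply(sim_q[, , k, drop = FALSE], 2, stats::quantile,
                          probs = 0.025),
        sim_upper = apply(sim_q[, , k, drop = FALSE], 2, stats::quantile,
                          probs = 0.975))
      out[[length(out) + 1L]] <- bins_k
    }
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  structure(list(bins = bins, n_replicates = n_replicates,
                 merged_bins = merged_any, probs = probs),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("VPC with", x$n_replicates, "replicate cohorts;",
      length(unique(paste(x$bins$channel, x$bins$time))), "bins\n")
  med <- x$bins[x$bins$percentile == 0.5, , drop = FALSE]
  cov <- mean(med$observed >= med$sim_lower & med$observed <= med$sim_upper)
  cat(sprintf("  observed medians inside simulated 95%% CI: %.0f%% of bins\n",
              100 * cov))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Observed percentiles (lines) over the simulated 95% confidence bands
#' (ribbons), faceted by observation channel.
#'
#' @param x A `vpc_result`.
#' @param log_y Plot the y axis on the log scale (concentrations span two
#'   orders of magnitude).
#' @return A ggplot object.
#' @export
plot_vpc <- function(x, log_y = FALSE) {
  stopifnot(inherits(x, "vpc_result"))
  b <- x$bins
  b$pct <- factor(paste0(100 * b$percentile, "th"))
  p <- ggplot2::ggplot(b, ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_lower, ymax = sim_upper,
                                      fill = pct), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = sim_median, colour = pct),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = observed, colour = pct)) +
    ggplot2::geom_point(ggplot2::aes(y = observed, colour = pct)) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "prediction-corrected value",
                  colour = "percentile", fill = "percentile")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
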