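# Three-hidden-state (D, I, O), nine-emission-state discrete HMM over P2
# series: Gaussian-mixture-derived emission binning, Baum-Welch training,
# Viterbi decoding, domain composition tables and dwell-time lifetimes.

#' Emission binning from low/high order Gaussian components
#'
#' The P2 observable space is partitioned into nine emission states from
#' the two-component normal mixture of the pooled P2 distribution: symbol 0
#' for P2 < mu_L, symbol 8 for P2 > mu_O, and seven interior bins of width
#' delta_P2 = (mu_O - mu_L)/7 in between.
#'
#' @param mu_L,sigma_L mean and SD of the low-order component.
#' @param mu_O,sigma_O mean and SD of the high-order component.
#' @return object of class `emission_binning` with `delta_p2` and the eight
#'   interior `edges` (the first edge is mu_L, the last mu_O).
#' @export
emission_binning <- function(mu_L, sigma_L, mu_O, sigma_O) {
  stopifnot(mu_L < mu_O, sigma_L > 0, sigma_O > 0)
  delta <- (mu_O - mu_L) / 7
  structure(list(mu_L = mu_L, sigma_L = sigma_L,
                 mu_O = mu_O, sigma_O = sigma_O,
                 delta_p2 = delta, edges = mu_L + (0:7) * delta),
            class = "emission_binning")
}

#' Fit the two-component emission mixture to pooled P2 samples
#'
#' Expectation-maximization fit (via \pkg{mclust}) of a two-component
#' normal mixture with unequal variances; the lower-mean component becomes
#' (mu_L, sigma_L), the higher (mu_O, sigma_O).  Overlapping components
#' (|mu_O - mu_L| <= 2 min(sigma), Behboodian's unimodality condition)
#' trigger a unimodal warning but the fit is still returned.
#'
#' @param p2 numeric vector of pooled P2 samples (>= 200), or a
#'   `p2_series` from [compute_p2()] pooled with `lipid_type`/`leaflet`.
#' @param lipid_type,leaflet optional filters when `p2` is a `p2_series`.
#' @return an [emission_binning()].
#' @export
fit_emission_gmm <- function(p2, lipid_type = NULL, leaflet = NULL) {
  x <- pool_p2(p2, lipid_type, leaflet)
  if (length(x) < 200L) stop("need at least 200 pooled P2 samples")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  o <- order(mu)
  b <- emission_binning(mu[o[1]], sig[o[1]], mu[o[2]], sig[o[2]])
  # Behboodian's sufficient condition: a two-component normal mixture is
  # unimodal whenever the means are within 2 min(sigma) of each other
  if (abs(b$mu_O - b$mu_L) <= 2 * min(b$sigma_L, b$sigma_O))
    warning("emission mixture looks unimodal: components overlap strongly")
  b
}

pool_p2 <- function(p2, lipid_type = NULL, leaflet = NULL) {
  if (inherits(p2, "p2_series")) {
    keep <- rep(TRUE, length(p2$lipid_ids))
    if (!is.null(lipid_type)) keep <- keep & p2$lipid_type == lipid_type
    m <- p2$values[, keep, drop = FALSE]
    if (!is.null(leaflet)) {
      lf <- p2$leaflet[, keep, drop = FALSE]
      m[lf != leaflet] <- NA
    }
    as.vector(m[!is.na(m)])
  } else as.numeric(p2[!is.na(p2)])
}

#' Map P2 values to emission symbols 0..8
#'
#' Symbol 0 when P2 < mu_L, symbol 8 when P2 > mu_O, interior symbol i when
#' mu_L + (i-1) delta <= P2 <= mu_L + i delta; boundary ties go to the
#' lower-indexed interior state.
#'
#' @param p2 numeric vector/matrix of P2 values, or a `p2_series`.
#' @param binning an [emission_binning()].
#' @return integer symbols with the shape of the input values.
#' @export
bin_emissions <- function(p2, binning) {
  x <- if (inherits(p2, "p2_series")) p2$values else p2
  s <- pmin(ceiling((x - binning$mu_L) / binning$delta_p2), 7)
  s <- pmax(s, 1)
  s[x < binning$mu_L] <- 0
  s[x > binning$mu_O] <- 8
  storage.mode(s) <- "integer"
  dim(s) <- dim(x)
  s
}

#' Initialize the 3-state HMM from an emission binning
#'
#' Emission rows are the integrals of the component normal distributions
#' over the nine bins (tails for the two unbounded end bins), renormalized.
#' The intermediate state uses mu_I = (sigma_L mu_O + sigma_O mu_L) /
#' (sigma_O + sigma_L) and sigma_I = min(|mu_O - mu_I|, |mu_L - mu_I|)/3,
#' placing its emission mass within 3 sigma of both bounds.  The start
#' distribution is uniform; the initial transition matrix is sticky
#' diagonal (order states persist for tens of ns at 1 ns sampling).
#'
#' @param binning an [emission_binning()].
#' @param sticky initial self-transition probability.
#' @return object of class `hmm_model` (untrained), states ordered D, I, O.
#' @export
init_hmm <- function(binning, sticky = 0.98) {
  mu_I <- (binning$sigma_L * binning$mu_O + binning$sigma_O * binning$mu_L) /
    (binning$sigma_O + binning$sigma_L)
  sigma_I <- min(abs(binning$mu_O - mu_I), abs(binning$mu_L - mu_I)) / 3
  breaks <- c(-Inf, binning$edges, Inf)
  row_for <- function(mu, sig) {
    p <- diff(pnorm(breaks, mu, sig))
    p / sum(p)
  }
  emit <- rbind(D = row_for(binning$mu_L, binning$sigma_L),
                I = row_for(mu_I, sigma_I),
                O = row_for(binning$mu_O, binning$sigma_O))
  colnames(emit) <- as.character(0:8)
  off <- (1 - sticky) / 2
  trans <- matrix(off, 3, 3, dimnames = list(c("D", "I", "O"),
                                             c("D", "I", "O")))
  diag(trans) <- sticky
  structure(list(start_prob = setNames(rep(1 / 3, 3), c("D", "I", "O")),
                 trans = trans, emit = emit, binning = binning,
                 mu_I = mu_I, sigma_I = sigma_I, trained = FALSE,
                 log_likelihood_trace = numeric(0)),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model>", if (x$trained) "trained" else "untrained",
      "| 3 states (D, I, O) x 9 emission symbols\n")
  cat("  self-transitions:",
      paste(sprintf("%s=%.3f", rownames(x$trans), diag(x$trans)),
            collapse = " "), "\n")
  invisible(x)
}

#' Baum-Welch training on emission-symbol sequences
#'
#' Multi-sequence Baum-Welch; iterates until the relative log-likelihood
#' change falls below `tol` or `maxiter` iterations.  After training,
#' hidden states are relabeled by their emission-weighted mean symbol
#' (lowest -> D, highest -> O) so labels are stable across runs.
#'
#' @param model an [init_hmm()] model.
#' @param sequences list of integer vectors of symbols 0..8 (or a symbol
#'   matrix, one column per lipid), each of length >= 2.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxiter iteration cap.
#' @return the trained `hmm_model` with `log_likelihood_trace` filled.
#' @export
train_hmm <- function(model, sequences, tol = 1e-6, maxiter = 500L) {
  seqs <- as_symbol_list(sequences)
  if (length(seqs) == 0L) stop("no emission sequences supplied")
  stopifnot(all(vapply(seqs, length, integer(1)) >= 2L))
  fit <- cpp_baum_welch(seqs, model$start_prob, model$trans, model$emit,
                        tol, as.integer(maxiter))
  perm <- order(as.vector(fit$emit %*% 0:8))
  model$start_prob <- setNames(fit$start[perm], c("D", "I", "O"))
  model$trans <- fit$trans[perm, perm]
  dimnames(model$trans) <- list(c("D", "I", "O"), c("D", "I", "O"))
  model$emit <- fit$emit[perm, ]
  dimnames(model$emit) <- list(c("D", "I", "O"), as.character(0:8))
  model$log_likelihood_trace <- fit$loglik
  model$trained <- TRUE
  model
}

as_symbol_list <- function(x) {
  if (is.list(x)) lapply(x, function(v) as.integer(v))
  else if (is.matrix(x)) lapply(seq_len(ncol(x)), function(j) as.integer(x[, j]))
  else list(as.integer(x))
}

#' Viterbi decoding of order states
#'
#' Maximum a posteriori state path per lipid; ties broken toward the
#' lower state index (D < I < O).
#'
#' @param model a trained [train_hmm()] model.
#' @param symbols integer vector, matrix (frames x lipids) or list of
#'   symbol sequences.
#' @param lipid_ids,lipid_type,times optional metadata carried along.
#' @return object of class `state_trajectory`: `states` (frames x lipids
#'   character matrix with entries "D"/"I"/"O"), `lipid_ids`, `lipid_type`,
#'   `times`.
#' @export
decode_states <- function(model, symbols, lipid_ids = NULL,
                          lipid_type = NULL, times = NULL) {
  if (!model$trained) stop("model must be trained before decoding")
  seqs <- as_symbol_list(symbols)
  labs <- c("D", "I", "O")
  paths <- lapply(seqs, function(s)
    labs[cpp_viterbi(s, model$start_prob, model$trans, model$emit) + 1L])
  states <- do.call(cbind, paths)
  structure(list(states = states,
                 lipid_ids = lipid_ids %||% seq_len(ncol(states)),
                 lipid_type = lipid_type %||%
                   rep("lipid", ncol(states)),
                 times = times %||% seq_len(nrow(states))),
            class = "state_trajectory")
}

#' Forward log-likelihood of a symbol sequence
#' @param model a trained or initialized `hmm_model`.
#' @param symbols integer vector of emission symbols 0..8.
#' @return total log-likelihood (all paths summed).
#' @export
forward_loglik <- function(model, symbols) {
  cpp_forward_loglik(as.integer(symbols), model$start_prob, model$trans,
                     model$emit)
}

#' Log-probability of one explicit state path
#' @param model `hmm_model`.
#' @param symbols emission symbols 0..8.
#' @param path integer state indices 1..3 or labels in D/I/O.
#' @return joint log-probability of (path, symbols).
#' @export
path_loglik <- function(model, symbols, path) {
  if (is.character(path)) path <- match(path, c("D", "I", "O"))
  symbols <- as.integer(symbols) + 1L
  lp <- log(model$start_prob[path[1]]) + log(model$emit[path[1], symbols[1]])
  if (length(path) > 1L) {
    for (t in 2:length(path))
      lp <- lp + log(model$trans[path[t - 1], path[t]]) +
        log(model$emit[path[t], symbols[t]])
  }
  unname(lp)
}

#' Stationary distribution of a trained model's transition matrix
#' @param model `hmm_model` or a square row-stochastic matrix.
#' @return named stationary probability vector.
#' @export
stationary_distribution <- function(model) {
  tr <- if (inherits(model, "hmm_model")) model$trans else model
  ev <- eigen(t(tr))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  setNames(v / sum(v), rownames(tr))
}

#' Full HMM classification pipeline for a P2 series
#'
#' Per (lipid type, leaflet) group: pool P2, fit the emission mixture,
#' discretize, initialize, train with Baum-Welch and decode with Viterbi.
#' With `reference` (a list of per-group trained models or a single
#' `hmm_model`), the supplied binning and matrices are used unchanged for
#' decoding, supporting comparisons across systems/temperatures against a
#' designated reference run.
#'
#' @param p2 a `p2_series` from [compute_p2()].
#' @param by_leaflet train separately per leaflet (default) or pooled.
#' @param reference optional frozen model(s) keyed by `"type|leaflet"`.
#' @param ... passed to [train_hmm()].
#' @return list with `states` (a merged `state_trajectory` over all
#'   lipids), `models` (per group), `binnings` (per group).
#' @export
hmm_classify <- function(p2, by_leaflet = TRUE, reference = NULL, ...) {
  nf <- nrow(p2$values)
  nl <- length(p2$lipid_ids)
  modal_leaflet <- apply(p2$leaflet, 2, function(v)
    names(sort(table(v), decreasing = TRUE))[1])
  group <- if (by_leaflet) paste(p2$lipid_type, modal_leaflet, sep = "|")
  else p2$lipid_type
  states <- matrix(NA_character_, nf, nl)
  models <- list(); binnings <- list()
  for (g in unique(group)) {
    cols <- which(group == g)
    pooled <- as.vector(p2$values[, cols])
    if (!is.null(reference)) {
      model <- if (inherits(reference, "hmm_model")) reference
      else reference[[g]] %||% reference[[p2$lipid_type[cols[1]]]]
      if (is.null(model)) stop("no reference model for group ", g)
      binning <- model$binning
    } else {
      binning <- fit_emission_gmm(pooled)
      model <- train_hmm(init_hmm(binning),
                         bin_emissions(p2$values[, cols, drop = FALSE],
                                       binning), ...)
    }
    sym <- bin_emissions(p2$values[, cols, drop = FALSE], binning)
    dec <- decode_states(model, sym)
    states[, cols] <- dec$states
    models[[g]] <- model; binnings[[g]] <- binning
  }
  st <- structure(list(states = states, lipid_ids = p2$lipid_ids,
                       lipid_type = p2$lipid_type, times = p2$times),
                  class = "state_trajectory")
  list(states = st, models = models, binnings = binnings)
}

#' Domain composition and distribution tables
#'
#' Two views over all frame-lipid observations: `composition` gives, per
#' hidden state, the percentage contributed by each lipid type (rows sum to
#' 100); `distribution` gives the percentage of all observations found in
#' each state.  Standard errors come from block averaging over time blocks.
#'
#' @param states a `state_trajectory` (or list of them, merged).
#' @param n_blocks number of time blocks for the standard errors.
#' @return list of data.frames `composition` (state, lipid_type, percent,
#'   se) and `distribution` (state, percent, se).
#' @export
domain_fractions <- function(states, n_blocks = 10L) {
  if (!inherits(states, "state_trajectory") && is.list(states))
    states <- merge_state_trajectories(states)
  st <- states$states
  nf <- nrow(st)
  labs <- c("D", "I", "O")
  types <- unique(states$lipid_type)
  blocks <- split(seq_len(nf),
                  cut(seq_len(nf), breaks = min(n_blocks, nf), labels = FALSE))
  dist_blocks <- t(vapply(blocks, function(rows) {
    tab <- table(factor(st[rows, , drop = FALSE], levels = labs))
    100 * as.vector(tab) / sum(tab)
  }, numeric(3)))
  distribution <- data.frame(
    state = labs,
    percent = vapply(labs, function(l)
      100 * mean(st == l), numeric(1)),
    se = apply(dist_blocks, 2, sd) / sqrt(nrow(dist_blocks)))
  comp_rows <- list()
  for (l in labs) {
    per_block <- t(vapply(blocks, function(rows) {
      sel <- st[rows, , drop = FALSE] == l
      cnt <- vapply(types, function(tp)
        sum(sel[, states$lipid_type == tp, drop = FALSE]), numeric(1))
      if (sum(cnt) == 0) rep(NA_real_, length(types))
      else 100 * cnt / sum(cnt)
    }, numeric(length(types))))
    dim(per_block) <- c(length(blocks), length(types))
    sel_all <- st == l
    cnt_all <- vapply(types, function(tp)
      sum(sel_all[, states$lipid_type == tp, drop = FALSE]), numeric(1))
    pct <- if (sum(cnt_all) > 0) 100 * cnt_all / sum(cnt_all)
    else rep(NA_real_, length(types))
    comp_rows[[l]] <- data.frame(
      state = l, lipid_type = types, percent = pct,
      se = apply(per_block, 2, function(v)
        sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))))
  }
  composition <- do.call(rbind, comp_rows)
  rownames(composition) <- NULL
  list(composition = composition, distribution = distribution)
}

merge_state_trajectories <- function(lst) {
  structure(list(states = do.call(cbind, lapply(lst, `[[`, "states")),
                 lipid_ids = unlist(lapply(lst, `[[`, "lipid_ids")),
                 lipid_type = unlist(lapply(lst, `[[`, "lipid_type")),
                 times = lst[[1]]$times),
            class = "state_trajectory")
}

#' Dwell-time histogram and double-exponential lifetime fit
#'
#' A dwell is a maximal run of consecutive frames a lipid spends in one
#' hidden state.  Dwells truncated by the trajectory ends are censored and
#' excluded from the fit (but kept, flagged, in the histogram data).  The
#' time-weighted histogram (each dwell of length L contributes weight L) is
#' fitted with a1 exp(-t/tau1) + a2 exp(-t/tau2) over \[0, fit_window\].
#'
#' @param states a `state_trajectory`.
#' @param state `"D"` or `"O"` (or `"I"`).
#' @param fit_window fit range in ns.
#' @param lipid_type optional restriction to one lipid type.
#' @param bin_width histogram bin width in ns (default one frame).
#' @return object of class `dwell_histogram`: `dwells` data.frame
#'   (length_ns, censored, lipid), `hist` data.frame (t, weight), fitted
#'   `fit_tau1 <= fit_tau2`, `fit_a1`, `fit_a2`, `fit_window`; the fit
#'   fields are `NA` (with a message) when fewer than 20 uncensored dwells
#'   exist.
#' @export
dwell_lifetimes <- function(states, state, fit_window = 300,
                            lipid_type = NULL, bin_width = NULL) {
  dt <- if (length(states$times) > 1L)
    diff(states$times[1:2]) / 1000 else 1      # ps -> ns
  if (dt <= 0 || !is.finite(dt)) dt <- 1
  cols <- seq_len(ncol(states$states))
  if (!is.null(lipid_type)) cols <- which(states$lipid_type == lipid_type)
  dw <- list()
  for (j in cols) {
    r <- rle(states$states[, j])
    n <- length(r$lengths)
    keep <- r$values == state
    if (!any(keep)) next
    cens <- logical(n); cens[1] <- TRUE; cens[n] <- TRUE
    dw[[length(dw) + 1L]] <- data.frame(
      length_ns = r$lengths[keep] * dt, censored = cens[keep],
      lipid = states$lipid_ids[j])
  }
  dwells <- if (length(dw)) do.call(rbind, dw) else
    data.frame(length_ns = numeric(0), censored = logical(0),
               lipid = integer(0))
  bw <- bin_width %||% dt
  fit <- list(tau1 = NA_real_, tau2 = NA_real_, a1 = NA_real_,
              a2 = NA_real_)
  hist_df <- data.frame(t = numeric(0), weight = numeric(0))
  usable <- dwells[!dwells$censored, , drop = FALSE]
  if (nrow(usable) > 0L) {
    breaks <- seq(0, max(usable$length_ns) + bw, by = bw)
    bin <- cut(usable$length_ns, breaks, include.lowest = TRUE)
    w <- tapply(usable$length_ns, bin, sum, default = 0)
    hist_df <- data.frame(t = head(breaks, -1) + bw / 2,
                          weight = as.vector(w))
  }
  if (nrow(usable) < 20L) {
    message("fewer than 20 uncensored dwells: lifetime fit refused")
  } else {
    hfit <- hist_df[hist_df$t <= fit_window & hist_df$weight > 0, ]
    m <- mean(usable$length_ns)
    start <- list(a1 = max(hfit$weight), tau1 = m / 2,
                  a2 = max(hfit$weight) / 4, tau2 = 2 * m)
    ft <- try(minpack.lm::nlsLM(
      weight ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2),
      data = hfit, start = start,
      lower = c(0, 1e-3, 0, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(ft, "try-error")) {
      cf <- coef(ft)
      if (cf[["tau1"]] <= cf[["tau2"]])
        fit <- list(tau1 = cf[["tau1"]], tau2 = cf[["tau2"]],
                    a1 = cf[["a1"]], a2 = cf[["a2"]])
      else
        fit <- list(tau1 = cf[["tau2"]], tau2 = cf[["tau1"]],
                    a1 = cf[["a2"]], a2 = cf[["a1"]])
    } else message("double-exponential lifetime fit failed to converge")
  }
  structure(list(dwells = dwells, hist = hist_df, state = state,
                 fit_tau1 = fit$tau1, fit_tau2 = fit$tau2,
                 fit_a1 = fit$a1, fit_a2 = fit$a2,
                 fit_window = fit_window),
            class = "dwell_histogram")
}
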