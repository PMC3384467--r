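# ---- batch-culture simulation and PHB fermentation metrics ----------------

#' Default batch-culture model parameters
#'
#' Two-substrate (glucose preferred, sucrose catabolite-repressed)
#' nitrogen-limited growth with PHB accumulation after nitrogen depletion.
#' States: residual cell mass `R` (g/L), PHB `P` (g/L), glucose `G` (g/L),
#' sucrose `S` (g/L), glutamate (MSG) `N` (g/L); cell dry weight is
#' `R + P` identically. Defaults emulate a shake-flask run on 1% (w/v)
#' glucose + 1.5% (w/v) sucrose with 0.2% (w/v) MSG: growth on both sugars
#' while glutamate lasts, sucrose uptake repressed while glucose is
#' plentiful, then PHB synthesis from the remaining sugars.
#'
#' @param mu_max_glc,mu_max_suc maximum specific growth rates (1/h) on
#'   glucose and sucrose.
#' @param qp_glc,qp_suc maximum specific PHB synthesis rates
#'   (g PHB / g RCM / h) from each sugar.
#' @param K_glc,K_suc Monod half-saturation constants (g/L).
#' @param K_msg half-saturation of growth on glutamate (g/L).
#' @param K_msg_inh glutamate level below which PHB synthesis switches on
#'   (g/L).
#' @param K_rep glucose level around which sucrose uptake is derepressed
#'   (g/L).
#' @param yield_x biomass yield on sugar (g RCM / g).
#' @param yield_p PHB yield on sugar (g PHB / g).
#' @param yield_n biomass yield on glutamate (g RCM / g MSG).
#' @param rcm0,phb0,glucose0,sucrose0,msg0 initial state (g/L).
#' @return Named list of parameters.
#' @export
culture_params <- function(mu_max_glc = 0.33, mu_max_suc = 0.20,
                           qp_glc = 0.052, qp_suc = 0.04,
                           K_glc = 0.2, K_suc = 0.2,
                           K_msg = 0.05, K_msg_inh = 0.02, K_rep = 0.3,
                           yield_x = 0.5, yield_p = 0.4, yield_n = 2.2,
                           rcm0 = 0.2, phb0 = 0.01, glucose0 = 10,
                           sucrose0 = 15, msg0 = 2) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stop("all culture parameters must be non-negative")
  p
}

#' Simulate a batch cultivation time series
#'
#' Integrates the nitrogen-limited two-substrate growth/PHB model of
#' [culture_params()] with `deSolve`. Growth requires glutamate and stops
#' at its depletion; PHB then accumulates with glucose preferred, sucrose
#' uptake being repressed while glucose exceeds the repression constant.
#' All state variables stay non-negative and CDW = RCM + PHB identically.
#'
#' @param params list from [culture_params()].
#' @param horizon cultivation length (h).
#' @param dt sampling interval (h).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param noise_sd optional additive measurement noise (g/L) applied to the
#'   sampled series (truncated at 0).
#' @return A `culture_series` data.frame: `t_h`, `cdw_gL`, `phb_gL`,
#'   `glucose_gL`, `sucrose_gL`, `msg_gL`.
#' @export
simulate_batch_culture <- function(params = culture_params(), horizon = 33,
                                   dt = 0.5, seed = 1L, noise_sd = 0) {
  stopifnot(dt > 0, horizon > 0)
  p <- params
  deriv <- function(t, y, parms) {
    R <- max(y[1L], 0); P <- max(y[2L], 0)
    G <- max(y[3L], 0); S <- max(y[4L], 0); N <- max(y[5L], 0)
    fN <- N / (p$K_msg + N)                 # growth needs glutamate
    phi <- p$K_msg_inh / (p$K_msg_inh + N)  # PHB switch on N depletion
    rep_s <- p$K_rep / (p$K_rep + G)        # sucrose catabolite repression
    mG <- p$mu_max_glc * G / (p$K_glc + G)
    mS <- p$mu_max_suc * S / (p$K_suc + S) * rep_s
    qG <- p$qp_glc * G / (p$K_glc + G)
    qS <- p$qp_suc * S / (p$K_suc + S) * rep_s
    dR <- (mG + mS) * fN * R
    dP <- (qG + qS) * phi * R
    dG <- -(mG * fN / p$yield_x + qG * phi / p$yield_p) * R
    dS <- -(mS * fN / p$yield_x + qS * phi / p$yield_p) * R
    dN <- -dR / p$yield_n
    list(c(dR, dP, dG, dS, dN))
  }
  y0 <- c(R = p$rcm0, P = p$phb0, G = p$glucose0, S = p$sucrose0,
          N = p$msg0)
  times <- seq(0, horizon, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda")
  sol <- as.data.frame(sol)
  for (col in c("R", "P", "G", "S", "N")) sol[[col]] <- pmax(sol[[col]], 0)
  if (noise_sd > 0) {
    sol <- with_seed(seed, {
      for (col in c("R", "P", "G", "S", "N"))
        sol[[col]] <- pmax(sol[[col]] +
                             stats::rnorm(nrow(sol), 0, noise_sd), 0)
      sol
    })
  }
  out <- data.frame(t_h = sol$time,
                    cdw_gL = sol$R + sol$P,     # CDW = RCM + PHB identically
                    phb_gL = sol$P,
                    glucose_gL = sol$G,
                    sucrose_gL = sol$S,
                    msg_gL = sol$N)
  structure(out, class = c("culture_series", "data.frame"))
}

#' Culture series CSV IO
#'
#' Header: `t_h,cdw_gL,phb_gL,glucose_gL,sucrose_gL,msg_gL` (substrate
#' columns optional on read).
#'
#' @param series a `culture_series` data.frame.
#' @param path file path.
#' @export
write_culture_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_culture_csv
#' @export
read_culture_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_h", "cdw_gL", "phb_gL")
  if (!all(need %in% names(df)))
    stop("culture CSV must have columns: ", paste(need, collapse = ", "))
  structure(df, class = c("culture_series", "data.frame"))
}

#' Fermentation metrics of a culture series
#'
#' Residual cell mass is CDW minus PHB concentration pointwise; PHB content
#' (wt%) is 100 times the ratio of PHB concentration to CDW; volumetric
#' productivity is the maximum PHB concentration divided by the elapsed
#' time from the first sample to the sample attaining it (switchable to the
#' total run time). Metrics operate on the raw samples; no smoothing or
#' interpolation is applied.
#'
#' @param series a `culture_series` (>= 2 time points, strictly increasing
#'   time, concentrations >= 0, PHB <= CDW everywhere).
#' @param productivity_basis `"max"` (time to the PHB maximum, default) or
#'   `"end"` (total run time).
#' @return A `culture_metrics`: list with `rcm_gL` (series),
#'   `phb_content_wtpct` (series, NA where CDW = 0), `max_phb_gL`,
#'   `max_phb_content_wtpct`, `volumetric_productivity_gLh`.
#' @examples
#' s <- data.frame(t_h = c(0, 10), cdw_gL = c(2, 10), phb_gL = c(0, 4))
#' compute_metrics(s)$max_phb_content_wtpct   # 40
#' @export
compute_metrics <- function(series,
                            productivity_basis = c("max", "end")) {
  productivity_basis <- match.arg(productivity_basis)
  s <- as.data.frame(series)
  if (nrow(s) < 2L) stop("at least 2 time points required")
  if (any(diff(s$t_h) <= 0)) stop("time must be strictly increasing")
  if (any(s$cdw_gL < 0) || any(s$phb_gL < 0))
    stop("concentrations must be non-negative")
  if (any(s$phb_gL > s$cdw_gL + 1e-9))
    stop("PHB exceeds CDW at some time point")
  if (any(s$cdw_gL == 0 & s$phb_gL > 0))
    stop("CDW is zero at a point with positive PHB")
  rcm <- s$cdw_gL - s$phb_gL
  content <- ifelse(s$cdw_gL > 0, 100 * s$phb_gL / s$cdw_gL, NA_real_)
  i_max <- which.max(s$phb_gL)
  max_phb <- s$phb_gL[i_max]
  elapsed <- switch(productivity_basis,
                    max = s$t_h[i_max] - s$t_h[1L],
                    end = s$t_h[nrow(s)] - s$t_h[1L])
  prod <- if (elapsed > 0) max_phb / elapsed else 0
  structure(list(rcm_gL = rcm,
                 phb_content_wtpct = content,
                 max_phb_gL = max_phb,
                 max_phb_content_wtpct = max(content, na.rm = TRUE),
                 volumetric_productivity_gLh = prod),
            class = "culture_metrics")
}

#' @export
print.culture_metrics <- function(x, ...) {
  cat(sprintf(
    "PHB max %.2f g/L, max content %.1f wt%%, productivity %.3f g/L/h\n",
    x$max_phb_gL, x$max_phb_content_wtpct,
    x$volumetric_productivity_gLh))
  invisible(x)
}
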