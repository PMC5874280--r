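#' Goodness-of-fit statistics for paired temperature series
#'
#' The six statistics used throughout the package to assess hourly
#' temperature reconstructions: mean error (ME, simulated minus observed),
#' mean absolute error (MAE), root mean square deviation (RMSD), modified
#' index of agreement (MIA), Nash-Sutcliffe efficiency (NSE) and the squared
#' Pearson correlation (R2). MIA is the absolute-deviation (Legates-McCabe
#' d1) form of the index of agreement,
#' `1 - sum|obs - sim| / sum(|sim - mean(obs)| + |obs - mean(obs)|)`,
#' bounded in \[0, 1\]; it is also the calibration objective.
#'
#' Missing pairs are removed before computation. NSE, R2 and MIA are
#' undefined for a constant observed series and raise an error there.
#'
#' @param obs,sim Numeric vectors of equal length (>= 2), degrees C.
#' @return A single numeric value; [model_metrics()] returns all six as a
#'   named one-row data.frame (with `n`, the number of pairs used).
#' @examples
#' obs <- c(1, 2, 3); sim <- c(2, 2, 2)
#' me(obs, sim)   # 0
#' mae(obs, sim)  # 2/3
#' mia(obs, sim)  # 0
#' @name metrics
NULL

.paired <- function(obs, sim) {
  if (length(obs) != length(sim))
    stop("obs and sim must have equal length")
  keep <- !is.na(obs) & !is.na(sim)
  if (sum(keep) < 2) stop("need at least 2 non-missing pairs")
  list(obs = obs[keep], sim = sim[keep])
}

.need_varying_obs <- function(obs) {
  if (length(unique(obs)) == 1L)
    stop("observed series is constant; statistic undefined")
}

#' @rdname metrics
#' @export
me <- function(obs, sim) { p <- .paired(obs, sim); mean(p$sim - p$obs) }

#' @rdname metrics
#' @export
mae <- function(obs, sim) { p <- .paired(obs, sim); mean(abs(p$sim - p$obs)) }

#' @rdname metrics
#' @export
rmsd <- function(obs, sim) { p <- .paired(obs, sim); sqrt(mean((p$sim - p$obs)^2)) }

#' @rdname metrics
#' @export
r2 <- function(obs, sim) {
  p <- .paired(obs, sim)
  .need_varying_obs(p$obs)
  stats::cor(p$obs, p$sim)^2
}

#' @rdname metrics
#' @export
nse <- function(obs, sim) {
  p <- .paired(obs, sim)
  .need_varying_obs(p$obs)
  1 - sum((p$obs - p$sim)^2) / sum((p$obs - mean(p$obs))^2)
}

#' @rdname metrics
#' @export
mia <- function(obs, sim) {
  p <- .paired(obs, sim)
  .need_varying_obs(p$obs)
  ob <- mean(p$obs)
  denom <- sum(abs(p$sim - ob) + abs(p$obs - ob))
  1 - sum(abs(p$obs - p$sim)) / denom
}

#' @rdname metrics
#' @export
model_metrics <- function(obs, sim) {
  p <- .paired(obs, sim)
  data.frame(n = length(p$obs),
             me = me(p$obs, p$sim), mae = mae(p$obs, p$sim),
             rmsd = rmsd(p$obs, p$sim), mia = mia(p$obs, p$sim),
             r2 = r2(p$obs, p$sim), nse = nse(p$obs, p$sim))
}
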