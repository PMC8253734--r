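## Generative growth model for the pooled screen.
##
## Compound arms scale exponential growth by an end-point viability
## multiplier from a four-parameter log-logistic curve; CRISPR targeting arms
## split each line into an unedited fraction growing normally and an edited
## fraction growing with a fitness cost.  Expectations are deterministic;
## Poisson end-point noise models the finite pool (~1000 cells/line seeded).

#' Dose-response viability multiplier
#'
#' \deqn{V(d) = b + (1 - b) / (1 + (d / EC50)^h)}
#' with residual viability \eqn{b \in [0,1]}, \eqn{EC50 > 0} (uM) and Hill
#' coefficient \eqn{h > 0}.  \code{V(0) = 1}; \code{V} is non-increasing in
#' dose.
#'
#' @param dose dose in uM (0 allowed).
#' @param ec50,hill,residual curve parameters (vectorized over lines).
#' @return viability fraction in \code{[residual, 1]}.
#' @export
doseViability <- function(dose, ec50, hill, residual) {
  stopifnot(all(ec50 > 0), all(hill > 0),
            all(residual >= 0 & residual <= 1), all(dose >= 0))
  residual + (1 - residual) / (1 + (dose / ec50)^hill)
}

#' Grow a pool under one condition
#'
#' Expected cells after \code{t} days:
#' \itemize{
#' \item compound arm: \eqn{N_i(t) = N_i(0) \cdot 2^{g_i t} \cdot V_i(d)};
#' \item CRISPR targeting arm:
#'   \eqn{N_i(t) = N_i(0) [(1-e_i) 2^{g_i t} + e_i 2^{g_i (1-\delta_i) t}]},
#'   with editing fraction \eqn{e_i} and knockout fitness cost \eqn{\delta_i};
#' \item sgNT / sgNC arms: \eqn{\delta_i} treated as 0 (no on-target cut or a
#'   cut in a non-expressed intron);
#' \item spike-in lines are Cas9-dead, hence unaffected by CRISPR arms, but
#'   respond to compound per their own dose-response curve.
#' }
#' With \code{noise = TRUE} the realized pool is drawn Poisson around the
#' expectations (seeded).
#'
#' @param panel a \linkS4class{PanelAnnotation} with sim parameters.
#' @param pool0 starting \linkS4class{PoolState}.
#' @param armType "compound" or "crispr".
#' @param agent compound name, or sgRNA name for CRISPR arms.
#' @param dose dose in uM (compound arms; ignored for CRISPR).
#' @param t days of growth (>= 0).
#' @param seed RNG seed for the Poisson draw.
#' @param noise draw Poisson end-point noise (default) or return expectations.
#' @param ntAgents sgRNA names treated as non-cutting / neutral controls.
#' @return a \linkS4class{PoolState} at day \code{pool0@day + t}.
#' @export
simulatePoolGrowth <- function(panel, pool0, armType = c("compound", "crispr"),
                               agent = "DMSO", dose = 0, t = 5,
                               seed = NULL, noise = TRUE,
                               ntAgents = c("sgNT", "sgNC")) {
  armType <- match.arg(armType)
  if (t < 0) stop("negative growth time t = ", t)
  n0 <- cellNumbers(pool0)
  pan <- as.data.frame(panel)
  m <- match(names(n0), pan$cell_line_id)
  if (anyNA(m)) {
    stop("panel lacks annotation for line(s): ",
         paste(names(n0)[is.na(m)], collapse = ", "))
  }
  pan <- pan[m, ]
  g <- pan$doubling_rate
  expected <- if (armType == "compound") {
    if (dose > 0 && any(is.na(pan$ec50))) {
      stop("unknown agent '", agent,
           "': no dose-response parameters for line(s) ",
           paste(pan$cell_line_id[is.na(pan$ec50)], collapse = ", "))
    }
    V <- if (dose == 0) rep(1, nrow(pan)) else {
      doseViability(dose, pan$ec50, pan$hill, pan$residual)
    }
    n0 * 2^(g * t) * V
  } else {
    e <- ifelse(pan$is_spikein, 0, pan$edit_frac)      # spike-ins: Cas9-dead
    delta <- if (agent %in% ntAgents) 0 else pan$ko_cost
    if (!(agent %in% ntAgents) && any(is.na(delta) & !pan$is_spikein)) {
      stop("unknown agent '", agent, "': no knockout fitness cost annotated")
    }
    delta <- ifelse(is.na(delta), 0, delta)
    e <- ifelse(is.na(e), 0, e)
    n0 * ((1 - e) * 2^(g * t) + e * 2^(g * (1 - delta) * t))
  }
  realized <- if (noise) {
    .withSeed(seed, stats::rpois(length(expected), expected))
  } else expected
  names(realized) <- names(n0)
  PoolState(realized, day = pool0@day + t,
            armType = armType, agent = agent, dose = dose)
}

#' Seed a fresh pool at equal representation
#'
#' @param panel a \linkS4class{PanelAnnotation}.
#' @param cellsPerLine starting cells per line (default 1000, the pooling
#'   convention for a ~368-line collection).
#' @return a day-0 \linkS4class{PoolState}.
#' @export
seedPool <- function(panel, cellsPerLine = 1000) {
  n <- rep(cellsPerLine, nrow(panel))
  names(n) <- cellLineIds(panel)
  PoolState(n, day = 0)
}
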