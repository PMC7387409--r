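# Cohort-level simulation: arms -> mice -> cells, with ground truth.

# triangle-wave fold of coordinates into [lo, hi]
.reflectInto <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}

#' Simulate a multi-arm cohort of tracked cells
#'
#' Draws, for every mouse in every arm, a set of trajectories from the arm's
#' motion-model mixture, with the arm's speed multiplier applied to each
#' model's \code{speedScale}. Start positions are uniform over the field;
#' cells starting in the low-x collagen band carry the peritumoral ground
#' truth label, the rest intratumoral. Sub-seeds are fanned out from the
#' master seed via \code{\link{subSeed}} so the output is a pure function of
#' the spec.
#'
#' Arms are simulated with common random numbers: the sub-seed of cell c of
#' mouse m is the same in every arm, so arms differ only through their
#' configured multipliers and mixtures (a paired design that makes the
#' configured ordering of arm means a property of the generator rather than
#' of sampling luck).
#'
#' @param spec a \code{\linkS4class{CohortSpec}}.
#' @param geometry a \code{\linkS4class{SceneGeometry}}; supplies the field,
#'   frame interval and the periphery/core split.
#' @param nFrames frames per track.
#' @param margin um kept clear of the field edge when placing cells.
#' @param reflect fold trajectories leaving the field back inside
#'   (tissue-boundary handling, needed when tracks will be rendered);
#'   FALSE leaves the model dynamics untouched.
#' @return a list with \code{trackSets} (one \code{TrackSet} per mouse) and
#'   \code{groundTruth}, a data.frame with one row per cell: arm, mouse,
#'   cell_id, model, region, and the seed used.
#' @export
simulateCohort <- function(spec, geometry = SceneGeometry(),
                           nFrames = 61L, margin = 15, reflect = FALSE) {
  stopIfNot(is(spec, "CohortSpec"), "spec must be a CohortSpec")
  validObject(spec)
  validObject(geometry)
  stopIfNot(length(spec@arms) >= 1L, "empty arm list")

  dt <- geometry@frameInterval
  px <- geometry@pixelSize
  wUm <- geometry@fieldSize[2L] * px[1L]
  hUm <- geometry@fieldSize[1L] * px[2L]
  bandUm <- geometry@peripheryWidthPx * px[1L]

  trackSets <- list()
  gt <- list()
  for (a in seq_along(spec@arms)) {
    arm <- spec@arms[[a]]
    for (m in seq_len(arm$nMice)) {
      mouseId <- sprintf("%s_m%02d", arm$label, m)
      trs <- vector("list", arm$cellsPerMouse)
      for (cc in seq_len(arm$cellsPerMouse)) {
        sd <- subSeed(spec@seed, m, cc)  # shared across arms (paired design)
        draw <- withSeed(subSeed(sd, 0L), {
          list(k = sample.int(length(arm$models), 1L,
                              prob = arm$weights),
               start = c(stats::runif(1L, margin, wUm - margin),
                         stats::runif(1L, margin, hUm - margin)))
        })
        model <- arm$models[[draw$k]]
        model@speedScale <- model@speedScale * arm$speedMultiplier
        regionTrue <- if (draw$start[1L] < bandUm) "peritumoral"
                      else "intratumoral"
        cellId <- sprintf("%s_c%03d", mouseId, cc)
        tr <- simulateTrack(model, nFrames, dt, start = draw$start,
                            seed = sd, id = cellId, region = regionTrue)
        if (reflect) {
          tr@x <- .reflectInto(tr@x, 5, wUm - 5)
          tr@y <- .reflectInto(tr@y, 5, hUm - 5)
        }
        trs[[cc]] <- tr
        gt[[length(gt) + 1L]] <- data.frame(
          arm = arm$label, mouse = mouseId, cell_id = cellId,
          model = model@kind, region = regionTrue, seed = sd,
          stringsAsFactors = FALSE)
      }
      trackSets[[mouseId]] <- TrackSet(trs, mouse = mouseId,
                                       arm = arm$label)
    }
  }
  list(trackSets = trackSets,
       groundTruth = do.call(rbind, c(gt, list(make.row.names = FALSE))))
}

#' Default three-arm cohort mirroring a checkpoint-inhibitor study design
#'
#' A vehicle-control arm plus two treated arms with speed multipliers below
#' one, so treated cells travel slower and show shorter displacement, and
#' with more cells per mouse, emulating increased infiltration after
#' treatment. The motion-model mixture combines Levy-like search, ballistic
#' runs, confined motion and stationary probing.
#'
#' @param seed master seed.
#' @param nMice mice per arm.
#' @param cellsControl,cellsTreated cells per mouse in the control and
#'   treated arms.
#' @param baseSpeed control-arm characteristic speed, um/min.
#' @return a \code{\linkS4class{CohortSpec}} with arms
#'   \code{control}, \code{mono} (multiplier 0.4) and \code{combo} (0.5).
#' @export
defaultCohortSpec <- function(seed = 1L, nMice = 6L, cellsControl = 12L,
                              cellsTreated = 20L, baseSpeed = 4.6) {
  models <- list(
    MotionModel("levy", speedScale = baseSpeed, persistence = 0.3,
                levyExponent = 2, truncationStep = 25),
    MotionModel("ballistic", speedScale = baseSpeed),
    MotionModel("confined_brownian", speedScale = baseSpeed,
                confinementRadius = 10),
    MotionModel("stationary_probing", speedScale = baseSpeed)
  )
  mix <- c(0.4, 0.2, 0.3, 0.1)
  arm <- function(label, mult, cells) {
    list(label = label, nMice = nMice, cellsPerMouse = cells,
         models = models, weights = mix, speedMultiplier = mult)
  }
  CohortSpec(list(arm("control", 1.0, cellsControl),
                  arm("mono", 0.4, cellsTreated),
                  arm("combo", 0.5, cellsTreated)),
             seed = seed)
}
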