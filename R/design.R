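# Design-matrix construction for the Poisson encoding models.

#' Canonical encoding variables
#'
#' The six variables of the full model, in the fixed order used for
#' tie-breaking, plus the three candidate variables that are screened by
#' stepwise inclusion and the position-with-direction conjunction used by
#' the context model.
#' @export
ENCODING_VARIABLES <- c("linear_position", "run_phase", "trial_outcome",
                        "speed", "acceleration", "turning")

#' @rdname ENCODING_VARIABLES
#' @export
CANDIDATE_VARIABLES <- c(ENCODING_VARIABLES,
                         "trial_time", "trial_history", "trial_type")

one_hot <- function(f, levels) {
  m <- sapply(levels, function(l) as.numeric(!is.na(f) & f == l))
  colnames(m) <- levels
  m
}

#' Build a design matrix from a binned session
#'
#' Categorical variables enter as one-hot indicator blocks (10 columns for
#' linear position, 2 for run phase, 2 for trial outcome, 20 for position
#' with direction); continuous variables enter as single z-scored columns.
#' Column 1 is the intercept.
#'
#' @param binned a `binned_session` (or its `bins` tibble).
#' @param variables character vector of variable names.
#' @param rows optional logical vector selecting bins.
#' @return list with `X` (matrix incl. intercept), `cols` (named list of
#'   column indices per variable), `rows` (logical inclusion mask used).
#' @export
build_design_matrix <- function(binned, variables = ENCODING_VARIABLES,
                                rows = NULL) {
  bins <- if (inherits(binned, "binned_session")) binned$bins else binned
  bad <- setdiff(variables,
                 c(CANDIDATE_VARIABLES, "position_with_direction"))
  if (length(bad))
    abort(paste0("unknown encoding variable(s): ",
                 paste(bad, collapse = ", ")))
  rows <- rows %||% bins$included
  blocks <- list()
  for (v in variables) {
    blocks[[v]] <- switch(
      v,
      linear_position = {
        m <- one_hot(bins$position_bin, 1:10)
        colnames(m) <- paste0("pos", 1:10); m
      },
      run_phase = {
        m <- one_hot(bins$run_phase, c("to_reward", "to_trigger"))
        colnames(m) <- c("rp_to_reward", "rp_to_trigger"); m
      },
      trial_outcome = {
        m <- one_hot(bins$trial_outcome, c("rewarded", "omitted"))
        colnames(m) <- c("out_rewarded", "out_omitted"); m
      },
      speed = matrix(bins$speed_z, ncol = 1,
                     dimnames = list(NULL, "speed")),
      acceleration = matrix(bins$accel_z, ncol = 1,
                            dimnames = list(NULL, "acceleration")),
      turning = matrix(bins$turning_z, ncol = 1,
                       dimnames = list(NULL, "turning")),
      trial_time = matrix(bins$trial_time_slow, ncol = 1,
                          dimnames = list(NULL, "trial_time")),
      trial_history = matrix(bins$trial_history_rewarded, ncol = 1,
                             dimnames = list(NULL, "trial_history")),
      trial_type = matrix(bins$trial_type_rewarded, ncol = 1,
                          dimnames = list(NULL, "trial_type")),
      position_with_direction = {
        m <- matrix(0, nrow(bins), 20)
        colnames(m) <- paste0("pwd_",
                              rep(c("rew", "trig"), each = 10), 1:10)
        pb <- bins$position_bin
        rp <- bins$run_phase
        ok <- !is.na(pb) & rp %in% c("to_reward", "to_trigger")
        col <- ifelse(rp[ok] == "to_reward", 0L, 10L) + pb[ok]
        m[cbind(which(ok), col)] <- 1
        m
      })
  }
  Xv <- do.call(cbind, blocks)
  X <- cbind(`(Intercept)` = 1, Xv)[rows, , drop = FALSE]
  cols <- list()
  off <- 1L
  for (v in variables) {
    k <- ncol(blocks[[v]])
    cols[[v]] <- off + seq_len(k)
    off <- off + k
  }
  list(X = X, cols = cols, rows = rows)
}
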