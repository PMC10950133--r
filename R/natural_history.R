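# Natural history of age-related hearing loss: irreversible progression
# NORMAL -> MILD -> MODERATE -> SEVERE (forward jumps allowed, no recovery)
# competing with state-independent mortality from a gender-specific life
# table. DEAD is absorbing.

HEARING_STATES <- c("NORMAL", "MILD", "MODERATE", "SEVERE")

#' Construct a life table
#'
#' A life table holds the annual probability of death `q(x)` for every age
#' on the model horizon (55 to 110). The terminal probability `q(110)` must
#' be 1 so the horizon closes: nobody outlives the model.
#'
#' @param age Integer ages, must cover 55..110 contiguously.
#' @param qx Annual death probabilities, same length as `age`.
#' @param gender `"male"` or `"female"`.
#' @return An object of class `ha_life_table`.
#' @seealso [synth_life_table()], [read_life_table()]
#' @export
life_table <- function(age, qx, gender = c("male", "female")) {
  gender <- match.arg(gender)
  if (length(age) != length(qx)) stop("age and qx must have the same length", call. = FALSE)
  o <- order(age)
  age <- as.integer(age[o]); qx <- as.numeric(qx[o])
  if (age[1] > 55 || age[length(age)] < 110 || any(diff(age) != 1L))
    stop("life table must cover ages 55..110 in annual steps", call. = FALSE)
  if (any(qx < 0 | qx > 1)) stop("death probabilities must lie in [0,1]", call. = FALSE)
  i110 <- match(110L, age)
  if (abs(qx[i110] - 1) > 1e-12)
    stop("q(110) must equal 1 (horizon closure)", call. = FALSE)
  structure(list(age = age, qx = qx, gender = gender), class = "ha_life_table")
}

lt_q <- function(lt, age) {
  i <- match(as.integer(age), lt$age)
  if (anyNA(i)) stop("age ", paste(age[is.na(i)], collapse = ","), " outside life table range", call. = FALSE)
  lt$qx[i]
}

#' Read / write a life table CSV
#'
#' The on-disk format is a two-column CSV (`age`, `qx`), one file per
#' gender, matching the format emitted by [write_life_table()] and
#' [synth_life_table()] exports, so real national life tables can be
#' dropped in without code changes.
#'
#' @param path CSV file path.
#' @param gender Gender the file refers to.
#' @return `read_life_table()` an `ha_life_table`; `write_life_table()` the
#'   path, invisibly.
#' @export
read_life_table <- function(path, gender = c("male", "female")) {
  gender <- match.arg(gender)
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table CSV must have columns 'age' and 'qx'", call. = FALSE)
  life_table(df$age, df$qx, gender)
}

#' @rdname read_life_table
#' @param lt An `ha_life_table`.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(data.frame(age = lt$age, qx = lt$qx), path, row.names = FALSE)
  invisible(path)
}

#' Construct a hearing-loss transition model
#'
#' Holds the annual, conditional-on-survival probabilities of progressing
#' between hearing states, optionally varying by age band, together with a
#' global calibration scale factor (see [calibrate_to_prevalence()]).
#' Progression is "gradual": one-step transitions are at least as likely as
#' two-step, which are at least as likely as three-step, within every row
#' and age band.
#'
#' @param p Either a single 4x4 upper-triangular matrix of forward
#'   transition probabilities (rows/columns ordered NORMAL, MILD, MODERATE,
#'   SEVERE; the diagonal and lower triangle are ignored and recomputed as
#'   stay probabilities), or a list of such matrices, one per age band.
#' @param age_breaks When `p` is a list of `k` matrices, an increasing
#'   vector of `k - 1` cut ages: band `i` applies to ages in
#'   `[break[i-1], break[i])` with the first band starting at 55 and the
#'   last ending at 110.
#' @param scale Global multiplicative scale factor applied to all forward
#'   probabilities (set by calibration; default 1).
#' @return An object of class `ha_transition_model`.
#' @export
transition_model <- function(p, age_breaks = NULL, scale = 1) {
  if (is.matrix(p)) p <- list(p)
  if (!is.list(p) || !all(vapply(p, is.matrix, logical(1))))
    stop("p must be a 4x4 matrix or a list of 4x4 matrices", call. = FALSE)
  k <- length(p)
  if (is.null(age_breaks)) age_breaks <- integer(0)
  if (length(age_breaks) != k - 1L)
    stop("need length(age_breaks) == number of bands - 1", call. = FALSE)
  if (k > 1L && (is.unsorted(age_breaks, strictly = TRUE) ||
                 min(age_breaks) <= 55 || max(age_breaks) > 110))
    stop("age_breaks must be strictly increasing and inside (55, 110]", call. = FALSE)
  bands <- lapply(p, function(m) {
    if (!all(dim(m) == c(4L, 4L))) stop("each band matrix must be 4x4", call. = FALSE)
    m[lower.tri(m, diag = TRUE)] <- 0
    dimnames(m) <- list(HEARING_STATES, HEARING_STATES)
    if (any(m < 0)) stop("forward probabilities must be >= 0", call. = FALSE)
    if (any(rowSums(m) > 1 + 1e-12))
      stop("forward probabilities in a row must sum to <= 1", call. = FALSE)
    for (i in 1:3) {
      fwd <- m[i, (i + 1):4]
      if (any(diff(fwd) > 1e-12))
        stop("gradual ordering violated in row ", HEARING_STATES[i],
             ": p(i->i+1) >= p(i->i+2) >= p(i->i+3)", call. = FALSE)
    }
    m
  })
  structure(list(bands = bands, age_breaks = as.numeric(age_breaks), scale = scale),
            class = "ha_transition_model")
}

# Scaled forward-probability matrix applicable at a given age; rows are
# capped to sum to at most 1 (capping reported through attribute "capped").
progression_matrix <- function(tm, age) {
  band <- if (length(tm$age_breaks)) findInterval(age, tm$age_breaks) + 1L else 1L
  m <- tm$bands[[band]] * tm$scale
  rs <- rowSums(m)
  capped <- rs > 1
  if (any(capped)) m[capped, ] <- m[capped, ] / rs[capped]
  attr(m, "capped") <- any(capped)
  m
}

#' One row of the cycle transition matrix
#'
#' The full annual transition probabilities out of one state at one age:
#' death claims `q(age)` regardless of hearing state (mortality is
#' state-independent; hearing loss carries no excess mortality), and the
#' remaining `1 - q(age)` is split between staying and progressing
#' according to the conditional-on-survival progression probabilities.
#' DEAD is absorbing.
#'
#' @param tm An `ha_transition_model`.
#' @param lt An `ha_life_table`.
#' @param state One of `"NORMAL"`, `"MILD"`, `"MODERATE"`, `"SEVERE"`,
#'   `"DEAD"`.
#' @param age Age in years, within 55..110.
#' @return Named probability vector over the five states, summing to 1.
#' @examples
#' lt <- synth_life_table(gender = "male")
#' tm <- transition_model(matrix(c(0,0.05,0.01,0.001, rep(0,12)), 4, 4, byrow = TRUE))
#' transition_row(tm, lt, "NORMAL", 60)
#' @export
transition_row <- function(tm, lt, state, age) {
  state <- match.arg(state, HEALTH_STATES)
  if (age < 55 || age > 110) stop("age must lie in [55, 110]", call. = FALSE)
  out <- stats::setNames(numeric(5), HEALTH_STATES)
  if (state == "DEAD") {
    out["DEAD"] <- 1
    return(out)
  }
  q <- lt_q(lt, age)
  m <- progression_matrix(tm, age)
  i <- match(state, HEARING_STATES)
  fwd <- m[i, ]
  out[HEARING_STATES] <- (1 - q) * fwd
  out[state] <- (1 - q) * (1 - sum(fwd))
  out["DEAD"] <- q
  out
}

#' Modelled hearing-state prevalence among the alive
#'
#' Iterates the cohort from age 55 (everyone with normal hearing) to the
#' requested age and returns the distribution over the four hearing states
#' renormalised among survivors. Because mortality is state-independent it
#' cancels in the renormalisation, but the iteration carries it anyway so
#' age-varying life tables behave identically to the cohort engine.
#'
#' @inheritParams transition_row
#' @param age Target age (>= 55).
#' @return Named proportions over NORMAL/MILD/MODERATE/SEVERE, summing to 1.
#' @export
predicted_prevalence <- function(tm, lt, age) {
  if (age < 55) stop("age must be >= start age 55", call. = FALSE)
  occ <- c(1, 0, 0, 0)
  a <- 55
  while (a < age) {
    q <- lt_q(lt, a)
    m <- progression_matrix(tm, a)
    stay <- 1 - rowSums(m)
    occ <- (1 - q) * (occ * stay + as.vector(occ %*% m))
    a <- a + 1
  }
  stats::setNames(occ / sum(occ), HEARING_STATES)
}

any_hl_prevalence <- function(tm, lt, age) {
  1 - predicted_prevalence(tm, lt, age)[["NORMAL"]]
}

#' Calibrate progression probabilities to prevalence targets
#'
#' Applies a single global multiplicative scale factor to all forward
#' progression probabilities so that the modelled prevalence of any hearing
#' loss among survivors matches the target proportions at the target ages
#' as closely as possible (least squares), e.g. 25\% at age 70 and 50\% at
#' age 85. The scale factor is found by golden-section search on the sum of
#' squared prevalence errors over a bracket that keeps every transition row
#' a valid probability distribution; any-hearing-loss prevalence is
#' monotone in the scale factor, so the least-squares optimum is unique.
#'
#' @inheritParams transition_row
#' @param targets Data frame with columns `age` and `target` (proportion of
#'   the alive cohort with any hearing loss).
#' @param tolerance Acceptable absolute deviation from each target
#'   (default 0.01, i.e. one percentage point). If no single scale factor
#'   reaches every target within tolerance, a warning reports the best
#'   achievable prevalence per target; the best-fitting model is still
#'   returned.
#' @return The input model with its `scale` replaced by the calibrated
#'   factor, and attributes `achieved` (data frame of target vs achieved
#'   prevalence) and `capped` (whether any row had to be capped at
#'   probability mass 1).
#' @export
calibrate_to_prevalence <- function(tm, lt, targets, tolerance = 0.01) {
  stopifnot(is.data.frame(targets), all(c("age", "target") %in% names(targets)),
            nrow(targets) >= 1L)
  if (any(targets$target < 0 | targets$target > 1))
    stop("targets must lie in [0,1]", call. = FALSE)
  if (any(targets$age < 55 | targets$age > 110))
    stop("target ages must lie within the model horizon", call. = FALSE)
  base <- tm; base$scale <- 1
  max_rowsum <- max(vapply(base$bands, function(m) max(rowSums(m)), numeric(1)))
  if (max_rowsum <= 0) stop("transition model has no forward probability mass", call. = FALSE)
  upper <- 1 / max_rowsum  # largest scale before any row needs capping
  sse <- function(k) {
    cand <- base; cand$scale <- k
    sum((vapply(targets$age, function(a) any_hl_prevalence(cand, lt, a), numeric(1)) -
           targets$target)^2)
  }
  opt <- stats::optimize(sse, interval = c(0, upper), tol = 1e-10)
  k <- opt$minimum
  # snap to the boundary when the optimum sits against it
  if (sse(0) <= opt$objective) k <- 0
  if (sse(upper) < min(opt$objective, sse(0))) k <- upper
  out <- base; out$scale <- k
  achieved <- vapply(targets$age, function(a) any_hl_prevalence(out, lt, a), numeric(1))
  miss <- abs(achieved - targets$target) > tolerance
  if (any(miss)) {
    warning("calibration could not reach all prevalence targets within tolerance ",
            tolerance, "; best achievable: ",
            paste(sprintf("age %d: %.4f (target %.4f)", as.integer(targets$age[miss]),
                          achieved[miss], targets$target[miss]), collapse = "; "),
            call. = FALSE)
  }
  attr(out, "achieved") <- data.frame(age = targets$age, target = targets$target,
                                      achieved = achieved)
  attr(out, "capped") <- any(vapply(unique(c(55, tm$age_breaks)), function(a)
    isTRUE(attr(progression_matrix(out, a), "capped")), logical(1)))
  out
}

#' Read / write a transition model CSV
#'
#' Long-format CSV with columns `from_state`, `to_state`, `probability` and
#' optionally `age_band` (as `"lo-hi"`, e.g. `"55-69"`); without the column
#' a single band covering the whole horizon is assumed.
#'
#' @param path CSV file path.
#' @return `read_transition_model()` an `ha_transition_model`;
#'   `write_transition_model()` the path, invisibly.
#' @export
read_transition_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("from_state", "to_state", "probability")
  if (!all(need %in% names(df)))
    stop("transition CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!"age_band" %in% names(df)) df$age_band <- "55-110"
  bands_raw <- unique(df$age_band)
  parse_band <- function(b) as.numeric(strsplit(b, "-", fixed = TRUE)[[1]])
  lo <- vapply(bands_raw, function(b) parse_band(b)[1], numeric(1))
  o <- order(lo)
  bands_raw <- bands_raw[o]
  mats <- lapply(bands_raw, function(b) {
    sub <- df[df$age_band == b, ]
    m <- matrix(0, 4, 4, dimnames = list(HEARING_STATES, HEARING_STATES))
    for (r in seq_len(nrow(sub))) {
      fi <- match(sub$from_state[r], HEARING_STATES)
      ti <- match(sub$to_state[r], HEARING_STATES)
      if (is.na(fi) || is.na(ti) || ti <= fi)
        stop("invalid transition ", sub$from_state[r], " -> ", sub$to_state[r], call. = FALSE)
      m[fi, ti] <- sub$probability[r]
    }
    m
  })
  breaks <- if (length(bands_raw) > 1)
    vapply(bands_raw[-1], function(b) parse_band(b)[1], numeric(1)) else NULL
  transition_model(mats, age_breaks = breaks)
}

#' @rdname read_transition_model
#' @param tm An `ha_transition_model` (its scale factor is folded into the
#'   written probabilities).
#' @export
write_transition_model <- function(tm, path) {
  k <- length(tm$bands)
  los <- c(55, tm$age_breaks)
  his <- c(tm$age_breaks - 1, 110)
  rows <- list()
  for (b in seq_len(k)) {
    m <- tm$bands[[b]] * tm$scale
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[b]] <- data.frame(
        from_state = HEARING_STATES[idx[, 1]],
        to_state = HEARING_STATES[idx[, 2]],
        probability = m[idx],
        age_band = sprintf("%d-%d", as.integer(los[b]), as.integer(his[b]))
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.ha_transition_model <- function(x, ...) {
  cat("Hearing-loss transition model:", length(x$bands), "age band(s), scale =",
      signif(x$scale, 6), "\n")
  invisible(x)
}

#' @export
print.ha_life_table <- function(x, ...) {
  cat("Life table (", x$gender, "), ages ", min(x$age), "-", max(x$age),
      ", q(55) = ", signif(x$qx[x$age == 55], 4), "\n", sep = "")
  invisible(x)
}
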