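#' Repeated stratified train/test splits
#'
#' Partitions presence and (pseudo-)absence cells into train and test sets,
#' stratified by class, `n_repeats` times. Each repeat is an exact partition:
#' train and test are disjoint and their union is the input.
#'
#' @param occurrences,absences Integer vectors of presence / absence cell ids.
#' @param train_frac Fraction of each class used for training (default 0.8).
#' @param n_repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @return A list of length `n_repeats`; each element has `train_pres`,
#'   `test_pres`, `train_abs`, `test_abs`.
#' @export
split_train_test <- function(occurrences, absences, train_frac = 0.8,
                             n_repeats = 10, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) abort("train_frac must be in (0,1)")
  if (length(occurrences) < 5) abort("need at least 5 presences")
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      # clamp so both train and test keep >= 1 member of each class
      n_tp <- min(length(occurrences) - 1L,
                  max(1L, round(train_frac * length(occurrences))))
      n_ta <- if (length(absences) < 2) {
        length(absences)
      } else {
        min(length(absences) - 1L,
            max(1L, round(train_frac * length(absences))))
      }
      tp <- sample(occurrences, n_tp)
      ta <- sample(absences, n_ta)
      list(train_pres = tp, test_pres = setdiff(occurrences, tp),
           train_abs = ta, test_abs = setdiff(absences, ta))
    })
  })
}

#' Fit a stand-in habitat-suitability model
#'
#' A single regularity-free quadratic logistic scorer: presence/absence is
#' regressed on the standardized predictors and their squares, and the
#' fitted probability is returned for every cell. Quadratic terms let the
#' model recover unimodal (Gaussian-niche) responses. Zero-variance
#' predictors are dropped; if none remain the model degenerates to the
#' constant prevalence map with a warning. The fit has no random component,
#' so identical inputs give identical maps.
#'
#' @param train_pres,train_abs Cell ids of training presences / absences.
#' @param predictors Climate tibble (`cell_id` + variable columns) covering
#'   every cell to be scored.
#' @return A tibble `cell_id`, `suitability` (in `[0, 1]`).
#' @export
fit_suitability <- function(train_pres, train_abs, predictors) {
  suitability_scorer(train_pres, train_abs, predictors)(predictors)
}

# Train the quadratic logistic scorer and return a projection function
# climate-tibble -> suitability tibble, so one fitted model can score both
# the calibration stack and a future stack on the calibration scale.
suitability_scorer <- function(train_pres, train_abs, predictors) {
  vars <- climate_vars(predictors)
  x <- as.matrix(predictors[vars])
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!any(keep)) {
    warn("all predictors have zero variance; returning a constant map")
    p <- length(train_pres) / (length(train_pres) + length(train_abs))
    return(function(climate) {
      tibble(cell_id = climate$cell_id, suitability = p)
    })
  }
  ctr <- colMeans(x[, keep, drop = FALSE])
  scl <- apply(x[, keep, drop = FALSE], 2, sd)
  design <- function(climate) {
    z <- sweep(sweep(as.matrix(climate[vars[keep]]), 2, ctr), 2, scl, "/")
    xx <- cbind(z, z^2)
    colnames(xx) <- c(vars[keep], paste0(vars[keep], "_sq"))
    as.data.frame(xx)
  }
  df <- design(predictors)[match(c(train_pres, train_abs),
                                 predictors$cell_id), , drop = FALSE]
  df$y <- rep(c(1L, 0L), c(length(train_pres), length(train_abs)))
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  function(climate) {
    scores <- suppressWarnings(
      predict(fit, newdata = design(climate), type = "response"))
    tibble(cell_id = climate$cell_id, suitability = unname(scores))
  }
}

#' True skill statistic of a binary prediction
#'
#' TSS = sensitivity + specificity - 1, in `[-1, 1]`. Both observed classes
#' must be present, otherwise one component is undefined and an error is
#' raised.
#'
#' @param predicted,observed Logical/0-1 vectors over the same cells.
#' @param threshold Optional score cutoff recorded in the result.
#' @param replicate Optional replicate id recorded in the result.
#' @return A one-row tibble `sensitivity`, `specificity`, `tss`,
#'   `threshold`, `replicate`.
#' @export
compute_tss <- function(predicted, observed, threshold = NA_real_,
                        replicate = NA_integer_) {
  if (length(predicted) != length(observed)) abort("length mismatch")
  obs <- as.logical(observed); prd <- as.logical(predicted)
  if (all(obs) || !any(obs)) {
    abort("both observed classes must be present to compute TSS")
  }
  sens <- sum(prd & obs) / sum(obs)
  spec <- sum(!prd & !obs) / sum(!obs)
  tibble(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
         threshold = threshold, replicate = replicate)
}

#' Max-TSS binarization threshold
#'
#' Searches all unique observed scores plus the 0/1 endpoints for the cutoff
#' (applied as `score >= threshold`) that maximizes TSS; ties go to the
#' smallest candidate. If all scores are identical that score is returned
#' with a warning.
#'
#' @param suitability Numeric scores per cell.
#' @param observed Logical/0-1 truth per cell (both classes present).
#' @return A list with `threshold` and `evaluation` (a [compute_tss()] row).
#' @export
maxtss_threshold <- function(suitability, observed) {
  obs <- as.logical(observed)
  if (all(obs) || !any(obs)) {
    abort("both observed classes must be present to choose a threshold")
  }
  if (length(unique(suitability)) == 1) {
    warn("all suitability scores identical; threshold is that score")
    thr <- suitability[1]
    return(list(threshold = thr,
                evaluation = compute_tss(suitability >= thr, observed, thr)))
  }
  cand <- sort(unique(c(0, suitability, 1)))
  tss <- vapply(cand, function(t) {
    prd <- suitability >= t
    obs <- as.logical(observed)
    sum(prd & obs) / sum(obs) + sum(!prd & !obs) / sum(!obs) - 1
  }, 0.0)
  thr <- cand[which.max(tss)] # which.max returns the first (smallest) maximizer
  list(threshold = thr,
       evaluation = compute_tss(suitability >= thr, observed, thr))
}

#' Filter model replicates by TSS
#'
#' Retains evaluations with `tss >= min_tss` (inclusive). An empty result
#' marks the species as unmodellable; downstream code drops it with a log
#' entry.
#'
#' @param evals A tibble of [compute_tss()] rows.
#' @param min_tss Retention threshold (default 0.5).
#' @return The retained subset, with attribute `unmodellable` (TRUE/FALSE).
#' @export
filter_models <- function(evals, min_tss = 0.5) {
  out <- evals |> filter(.data$tss >= min_tss)
  attr(out, "unmodellable") <- nrow(out) == 0
  out
}

#' Cell-wise median ensemble of suitability maps
#'
#' @param maps A list of numeric vectors (or `suitability` tibbles) on the
#'   same cells. An even count averages the two middle values.
#' @return A numeric vector (or tibble, matching the input kind) of medians.
#' @export
ensemble_median <- function(maps) {
  if (length(maps) < 1) abort("need at least one map")
  tib <- is.data.frame(maps[[1]])
  vecs <- if (tib) lapply(maps, `[[`, "suitability") else maps
  n <- unique(lengths(vecs))
  if (length(n) != 1) abort("maps differ in length")
  m <- matrix(unlist(vecs), nrow = n[1])
  med <- apply(m, 1, median)
  if (tib) tibble(cell_id = maps[[1]]$cell_id, suitability = med) else med
}

#' Drop species below a minimum occurrence count
#'
#' @param presences Long tibble `species`, `cell_id`.
#' @param min_occ Minimum number of occupied cells (inclusive) to retain a
#'   species; the classic floor for distribution modelling is 20.
#' @return The filtered tibble, with attribute `removed` (species names).
#' @export
min_occurrence_filter <- function(presences, min_occ = 20) {
  if (nrow(presences) == 0) {
    attr(presences, "removed") <- character()
    return(presences)
  }
  sizes <- presences |> count(.data$species)
  drop <- sizes$species[sizes$n < min_occ]
  out <- presences |> filter(!(.data$species %in% drop))
  if (length(drop) > 0) {
    inform(sprintf("min_occurrence_filter: removed %d species below %d cells",
                   length(drop), min_occ))
  }
  attr(out, "removed") <- drop
  out
}
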