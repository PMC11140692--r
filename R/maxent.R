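#' De-duplicate occurrence points on a grid
#'
#' Keeps the first point per grid cell (insertion order) to avoid
#' overweighting densely sampled cells during model fitting.
#'
#' @param points data.frame with `x`, `y` and/or `cell` columns.
#' @param grid a [cg_raster] defining the cells (used when `cell` is
#'   absent).
#' @return an `occurrence_set`: data.frame `(x, y, cell)` with at most one
#'   row per cell; attribute `n_raw` records the input count.
#' @export
dedupe_occurrences <- function(points, grid) {
  if (!nrow(points)) stop("empty occurrence input", call. = FALSE)
  if (is.null(points$cell)) {
    nr <- nrow(grid$values)
    col <- pmin(pmax(ceiling((points$x - grid$xmin) / grid$pixel_size), 1),
                ncol(grid$values))
    row <- pmin(pmax(nr - floor((points$y - grid$ymin) / grid$pixel_size), 1),
                nr)
    points$cell <- (col - 1L) * nr + row
  }
  keep <- !duplicated(points$cell)
  out <- points[keep, c("x", "y", "cell")]
  rownames(out) <- NULL
  attr(out, "n_raw") <- nrow(points)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

stack_layer_values <- function(stack) {
  lapply(stack$layers, function(l) raster_values(l$raster))
}

retained_layers <- function(stack) {
  Filter(function(l) isTRUE(l$retained), stack$layers)
}

#' Prune correlated environmental variables
#'
#' Iteratively removes continuous layers until no retained pair has
#' `|r| >= r_threshold` (Pearson, over cells valid in both layers).
#' Within an offending pair the layer with the larger mean absolute
#' correlation to all other retained continuous layers is dropped.
#' Constant layers (undefined correlation) are dropped with a warning.
#' Manual `keep` / `drop` overrides are honoured.
#'
#' @param stack an `env_stack`.
#' @param r_threshold exclusion threshold on `|r|` (default 0.75).
#' @param keep,drop character vectors of layer names to force-retain /
#'   force-drop.
#' @return the stack with updated `retained` flags; attribute
#'   `"dropped"` lists removed layer names.
#' @export
prune_variables <- function(stack, r_threshold = 0.75,
                            keep = character(0), drop = character(0)) {
  for (nm in drop) stack$layers[[nm]]$retained <- FALSE
  cont <- names(Filter(function(l) l$type == "continuous" && isTRUE(l$retained),
                       stack$layers))
  vals <- lapply(cont, function(nm) raster_values(stack$layers[[nm]]$raster))
  names(vals) <- cont
  const <- cont[vapply(vals, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                         !is.finite(stats::sd(v, na.rm = TRUE)), logical(1))]
  for (nm in setdiff(const, keep)) {
    warning("dropping constant layer (undefined correlation): ", nm)
    stack$layers[[nm]]$retained <- FALSE
  }
  active <- setdiff(cont, setdiff(const, keep))
  while (length(active) >= 2) {
    M <- do.call(cbind, vals[active])
    cm <- abs(stats::cor(M, use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) < r_threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- active[worst]
    pair <- setdiff(pair, keep)
    if (!length(pair)) break   # both protected; leave the violation
    mean_abs <- colMeans(cm)[match(pair, active)]
    victim <- pair[which.max(mean_abs)]
    stack$layers[[victim]]$retained <- FALSE
    active <- setdiff(active, victim)
  }
  attr(stack, "dropped") <- setdiff(cont, active)
  stack
}

# Feature construction: continuous layers min-max scaled to [0,1] over the
# full grid; categorical layers expanded to one indicator per level.
# Returns list(F = cells x features matrix, vars = parent variable per
# feature, scale = per-feature (min, range) for continuous features).
stack_features <- function(stack) {
  layers <- retained_layers(stack)
  if (!length(layers)) stop("no retained layers in stack", call. = FALSE)
  cols <- list(); vars <- character(0); scales <- list()
  for (l in layers) {
    v <- raster_values(l$raster)
    if (l$type == "continuous") {
      lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
      rng <- if (hi > lo) hi - lo else 1
      cols[[l$name]] <- (v - lo) / rng
      vars <- c(vars, l$name)
      scales[[l$name]] <- c(min = lo, range = rng)
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      for (g in lev) {
        nm <- sprintf("%s=%g", l$name, g)
        cols[[nm]] <- as.numeric(v == g)
        vars <- c(vars, l$name)
      }
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- names(cols)
  list(F = F, vars = vars, scales = scales)
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Fit a maximum-entropy distribution model
#'
#' Selects the distribution over background cells that maximises entropy
#' subject to the presence-sample feature means, equivalently maximising
#' the L1-penalised presence log-likelihood
#' \deqn{\ell(\lambda) = \lambda' \bar f_{pres} - \log Z(\lambda)
#'       - \sum_j \beta_j |\lambda_j|,}
#' where `Z` sums `exp(lambda' f)` over background cells. Features are
#' linear terms in the (0-1 scaled) continuous layers plus one indicator
#' per categorical level. Optimisation is coordinate-wise Newton with
#' soft-thresholding and backtracking; every accepted update strictly
#' increases the objective, and the per-update gains are recorded per
#' variable (the basis of [percent_contribution()]).
#'
#' @param occ an [dedupe_occurrences()] result.
#' @param stack an `env_stack` (only retained layers are used).
#' @param background cells to use as background: `NULL` = all cells when
#'   at most `max_background`, else a seeded uniform sample.
#' @param beta_scale multiplier on the default regularisation
#'   `beta_j = beta_scale * sd(f_j over presences) / sqrt(n_pres)`.
#' @param beta optional explicit regularisation (scalar or per-feature
#'   vector), overriding the default rule.
#' @param tol convergence tolerance on the penalized objective change per
#'   full sweep.
#' @param max_iter maximum coordinate sweeps.
#' @param max_background background budget before sampling kicks in.
#' @param seed seed for background sampling.
#' @return a `maxent_model`: `lambda`, `beta`, `features`, `vars`,
#'   `scales`, `logZ`, `entropy`, `bg_cells`, `trace` (per-update gains),
#'   `converged`, `loglik`.
#' @export
fit_maxent <- function(occ, stack, background = NULL, beta_scale = 1,
                       beta = NULL, tol = 1e-9, max_iter = 1000,
                       max_background = 10000, seed = 1L) {
  feats <- stack_features(stack)
  ncells <- nrow(feats$F)
  if (nrow(occ) < 5) stop("need at least 5 presences", call. = FALSE)
  bg <- background
  if (is.null(bg)) {
    bg <- if (ncells <= max_background) seq_len(ncells) else
      with_seed(seed, sort(sample.int(ncells, max_background)))
  }
  Fb <- feats$F[bg, , drop = FALSE]
  keep_bg <- stats::complete.cases(Fb)
  bg <- bg[keep_bg]; Fb <- Fb[keep_bg, , drop = FALSE]
  Fp <- feats$F[occ$cell, , drop = FALSE]
  if (any(!is.finite(Fp))) stop("non-finite features at presence cells",
                                call. = FALSE)
  fbar <- colMeans(Fp)
  J <- ncol(Fb)
  if (is.null(beta)) {
    beta <- beta_scale * apply(Fp, 2, stats::sd) / sqrt(nrow(Fp))
    beta[!is.finite(beta)] <- 0
  } else {
    beta <- rep_len(beta, J)
  }

  lambda <- numeric(J)
  eta <- as.vector(Fb %*% lambda)
  obj <- function(lam, et) {
    sum(lam * fbar) - log_sum_exp(et) - sum(beta * abs(lam))
  }
  cur <- obj(lambda, eta)
  trace <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    start <- cur
    for (j in seq_len(J)) {
      logZ <- log_sum_exp(eta)
      p <- exp(eta - logZ)
      fj <- Fb[, j]
      m1 <- sum(p * fj)
      m2 <- sum(p * fj^2)
      h <- m2 - m1^2
      g <- fbar[j] - m1
      if (h < 1e-12) next
      # soft-thresholded Newton proposal on the quadratic model
      z <- lambda[j] + g / h
      prop <- sign(z) * max(abs(z) - beta[j] / h, 0)
      delta <- prop - lambda[j]
      if (abs(delta) < 1e-14) next
      delta <- max(min(delta, 2), -2)   # trust region; log-partition is not quadratic
      accepted <- FALSE
      for (half in 1:30) {
        lam_try <- lambda
        lam_try[j] <- lambda[j] + delta
        eta_try <- eta + delta * fj
        val <- obj(lam_try, eta_try)
        if (val > cur) {
          trace[[length(trace) + 1]] <-
            c(feature = j, gain = val - cur)
          lambda <- lam_try; eta <- eta_try; cur <- val
          accepted <- TRUE
          break
        }
        delta <- delta / 2
      }
    }
    if (abs(cur - start) < tol) { converged <- TRUE; break }
  }
  logZ <- log_sum_exp(eta)
  p <- exp(eta - logZ)
  H <- -sum(p * ifelse(p > 0, log(p), 0))
  tr <- if (length(trace)) {
    tm <- do.call(rbind, trace)
    data.frame(feature = colnames(Fb)[tm[, "feature"]],
               variable = feats$vars[tm[, "feature"]],
               gain = tm[, "gain"])
  } else {
    data.frame(feature = character(0), variable = character(0),
               gain = numeric(0))
  }
  structure(
    list(lambda = stats::setNames(lambda, colnames(Fb)),
         beta = stats::setNames(beta, colnames(Fb)),
         features = colnames(Fb), vars = feats$vars, scales = feats$scales,
         logZ = logZ, entropy = H, bg_cells = bg,
         n_presences = nrow(occ), presence_cells = occ$cell,
         trace = tr, converged = converged, loglik = cur,
         stack_dim = dim(stack$layers[[1]]$raster$values),
         feature_matrix = feats$F),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features, %d presences, %d background cells\n",
    length(x$lambda), x$n_presences, length(x$bg_cells)))
  cat(sprintf("  penalized loglik %.4f, entropy %.3f, converged: %s\n",
              x$loglik, x$entropy, x$converged))
  invisible(x)
}

# raw (exponential-family) output for cells or a feature matrix
maxent_raw <- function(model, cells = NULL, F = NULL) {
  if (is.null(F)) {
    F <- if (is.null(cells)) model$feature_matrix[model$bg_cells, , drop = FALSE]
         else model$feature_matrix[cells, , drop = FALSE]
  }
  exp(as.vector(F %*% model$lambda) - model$logZ)
}

#' Logistic-scale suitability
#'
#' Transforms the raw output `r` to `tau * r * exp(H) / (1 + tau * r *
#' exp(H))` with `H` the entropy of the fitted distribution and `tau` the
#' assumed prevalence at typical conditions (default 0.5). Strictly
#' increasing in `r`, bounded in (0,1).
#'
#' @param model a fitted `maxent_model`.
#' @param cells cell indices (default: the background).
#' @param tau prevalence constant.
#' @param raw optionally supply raw values directly.
#' @return logistic suitabilities in (0,1).
#' @export
logistic_output <- function(model, cells = NULL, tau = 0.5, raw = NULL) {
  if (is.null(raw)) raw <- maxent_raw(model, cells)
  q <- tau * raw * exp(model$entropy)
  q / (1 + q)
}

#' Suitability raster over the whole grid
#'
#' @param model a fitted `maxent_model`.
#' @param stack the `env_stack` used for fitting (provides the grid).
#' @param tau prevalence constant for the logistic transform.
#' @return a [cg_raster] of logistic suitability.
#' @export
maxent_suitability <- function(model, stack, tau = 0.5) {
  template <- stack$layers[[1]]$raster
  ncells <- ncell(template)
  vals <- logistic_output(model, cells = seq_len(ncells), tau = tau)
  raster_like(template, vals)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a presence score exceeds a background score, ties
#' counted one half. Invariant under strictly increasing transforms of
#' the scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score sets must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Replicated subsampling evaluation
#'
#' Repeats a random 75/25 presence split `n_replicates` times: fit on the
#' training split, score the held-out presences against the background,
#' and average the suitability maps. (A k-fold mode assigns each presence
#' to exactly one test fold instead.)
#'
#' @param occ occurrence set.
#' @param stack environment stack.
#' @param train_fraction presences used for fitting per replicate.
#' @param n_replicates replicate count.
#' @param mode `"subsample"` (default) or `"kfold"` (uses `n_replicates`
#'   folds).
#' @param seed RNG seed for the splits.
#' @param ... passed to [fit_maxent()].
#' @return list with `auc` (per-replicate test AUC), `mean_auc`,
#'   `mean_map` (a [cg_raster]), `models`.
#' @export
evaluate_replicates <- function(occ, stack, train_fraction = 0.75,
                                n_replicates = 10, mode = c("subsample", "kfold"),
                                seed = 1L, ...) {
  mode <- match.arg(mode)
  n <- nrow(occ)
  n_train <- floor(train_fraction * n)
  if (n - n_train < 1 || n_train < 5) {
    stop("too few presences for a train/test split", call. = FALSE)
  }
  splits <- with_seed(seed, {
    if (mode == "subsample") {
      lapply(seq_len(n_replicates), function(i) sample.int(n, n_train))
    } else {
      fold <- sample(rep_len(seq_len(n_replicates), n))
      lapply(seq_len(n_replicates), function(i) which(fold != i))
    }
  })
  template <- stack$layers[[1]]$raster
  acc <- numeric(ncell(template))
  aucs <- numeric(length(splits))
  models <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    tr <- occ[splits[[i]], , drop = FALSE]
    te <- occ[-splits[[i]], , drop = FALSE]
    class(tr) <- class(occ)
    mod <- fit_maxent(tr, stack, seed = seed + i, ...)
    suit <- logistic_output(mod, cells = seq_len(length(acc)))
    acc <- acc + suit
    aucs[i] <- roc_auc(suit[te$cell], suit[mod$bg_cells])
    models[[i]] <- mod
  }
  list(auc = aucs, mean_auc = mean(aucs),
       mean_map = raster_like(template, acc / length(splits)),
       models = models)
}

#' Percent contribution of each environmental variable
#'
#' Attributes every accepted gain in the penalized objective during
#' fitting to the variable whose weight moved, sums per variable
#' (indicator features aggregate to their parent categorical variable)
#' and normalises to 100%. Interaction effects are implicitly shared
#' through the fitting path.
#'
#' @param model a fitted `maxent_model`.
#' @return named percentages summing to 100.
#' @export
percent_contribution <- function(model) {
  if (!nrow(model$trace)) stop("model carries no fitting trace", call. = FALSE)
  g <- tapply(model$trace$gain, model$trace$variable, sum)
  vars <- unique(model$vars)
  out <- stats::setNames(numeric(length(vars)), vars)
  out[names(g)] <- g
  100 * out / sum(out)
}

#' Permutation importance of each environmental variable
#'
#' For each variable, permutes its values across the presence and
#' background cells (all indicator features of a categorical variable
#' move together), recomputes the training AUC, and reports the mean AUC
#' drop over `n_perm` permutations, floored at zero and normalised to
#' sum to 100%.
#'
#' @param model a fitted `maxent_model`.
#' @param n_perm permutations per variable.
#' @param seed RNG seed.
#' @return named percentages summing to 100 (all zeros if no variable
#'   matters).
#' @export
permutation_importance <- function(model, n_perm = 10, seed = 1L) {
  cells <- c(model$presence_cells, model$bg_cells)
  np <- length(model$presence_cells)
  F0 <- model$feature_matrix[cells, , drop = FALSE]
  score <- function(F) {
    s <- as.vector(F %*% model$lambda)
    roc_auc(s[seq_len(np)], s[-seq_len(np)])
  }
  base <- score(F0)
  vars <- unique(model$vars)
  drops <- with_seed(seed, {
    vapply(vars, function(v) {
      jj <- which(model$vars == v)
      mean(vapply(seq_len(n_perm), function(k) {
        Fp <- F0
        perm <- sample(nrow(F0))
        Fp[, jj] <- F0[perm, jj, drop = FALSE]
        base - score(Fp)
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) return(stats::setNames(drops, vars))
  100 * drops / sum(drops)
}

#' Response curve of one variable
#'
#' Logistic output along a grid of the variable's values, holding every
#' other continuous variable at its background mean and every other
#' categorical variable at its background mode.
#'
#' @param model a fitted `maxent_model`.
#' @param variable variable name.
#' @param n grid points (continuous variables).
#' @param tau prevalence constant.
#' @return data.frame `(value, suitability)`.
#' @export
response_curve <- function(model, variable, n = 100, tau = 0.5) {
  if (!variable %in% model$vars) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  Fb <- model$feature_matrix[model$bg_cells, , drop = FALSE]
  base <- colMeans(Fb)
  # categorical variables: snap the base to the modal level's indicator set
  for (v in unique(model$vars)) {
    jj <- which(model$vars == v)
    if (length(jj) > 1 || grepl("=", model$features[jj[1]], fixed = TRUE)) {
      mode_j <- jj[which.max(colSums(Fb[, jj, drop = FALSE]))]
      base[jj] <- 0
      base[mode_j] <- 1
    }
  }
  jj <- which(model$vars == variable)
  if (length(jj) == 1 && !grepl("=", model$features[jj], fixed = TRUE)) {
    sc <- model$scales[[variable]]
    grid_scaled <- seq(0, 1, length.out = n)
    values <- sc["min"] + grid_scaled * sc["range"]
    F <- matrix(base, n, length(base), byrow = TRUE,
                dimnames = list(NULL, model$features))
    F[, jj] <- grid_scaled
  } else {
    values <- seq_along(jj)
    F <- matrix(base, length(jj), length(base), byrow = TRUE,
                dimnames = list(NULL, model$features))
    F[, jj] <- diag(length(jj))
    values <- sub(".*=", "", model$features[jj])
  }
  raw <- exp(as.vector(F %*% model$lambda) - model$logZ)
  data.frame(value = as.numeric(values),
             suitability = logistic_output(model, raw = raw, tau = tau))
}

#' Predict suitability for arbitrary feature rows
#'
#' @param object a fitted `maxent_model`.
#' @param newdata data.frame of variables on their original scales
#'   (continuous variables are rescaled with the training min/range;
#'   categorical variables by level).
#' @param type `"logistic"`, `"raw"` or `"exponent"` (the linear score).
#' @param tau prevalence constant for the logistic scale.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw", "exponent"),
                                 tau = 0.5, ...) {
  type <- match.arg(type)
  F <- matrix(0, nrow(newdata), length(object$features),
              dimnames = list(NULL, object$features))
  for (v in unique(object$vars)) {
    jj <- which(object$vars == v)
    if (!v %in% names(newdata)) stop("newdata lacks variable: ", v, call. = FALSE)
    if (length(jj) == 1 && !grepl("=", object$features[jj], fixed = TRUE)) {
      sc <- object$scales[[v]]
      F[, jj] <- (newdata[[v]] - sc["min"]) / sc["range"]
    } else {
      lev <- sub(".*=", "", object$features[jj])
      F[, jj] <- outer(as.character(newdata[[v]]), lev, "==") * 1
    }
  }
  eta <- as.vector(F %*% object$lambda)
  if (type == "exponent") return(eta)
  raw <- exp(eta - object$logZ)
  if (type == "raw") return(raw)
  logistic_output(object, raw = raw, tau = tau)
}

#' Threshold maximising sensitivity + specificity
#'
#' Candidate thresholds are the observed score values; sensitivity is the
#' fraction of presences scoring at or above the threshold and
#' specificity the fraction of background scoring below it. Ties resolve
#' to the lowest threshold.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return the selected threshold.
#' @export
threshold_max_ss <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  ss <- vapply(cand, function(t) {
    mean(presence_scores >= t) + mean(background_scores < t)
  }, numeric(1))
  cand[which.max(ss)]   # which.max takes the first (lowest) on ties
}

#' Tiered potential-distribution map
#'
#' Cells with suitability strictly above the threshold form the potential
#' region; within it, currently occupied cells are *highly* potential,
#' mangrove cells *least* potential (dense canopy resists invasion) and
#' tidal-flat or unmasked cells *moderately* potential. Mask precedence is
#' high > least > moderate. Also tabulates tier areas (hm^2) and
#' within-region percentages for the whole zone and any named sub-regions.
#'
#' @param suitability a [cg_raster] of suitability.
#' @param threshold potential/non-potential cut (strict `>`).
#' @param sa_mask,mangrove_mask,tidalflat_mask logical/0-1 [cg_raster]s
#'   co-registered with `suitability` (`NULL` = empty mask).
#' @param regions optional named list of logical/0-1 [cg_raster] region
#'   masks for sub-region tables.
#' @return a `tier_map`: `tiers` ([cg_raster]: 0 none, 1 least,
#'   2 moderate, 3 high), `threshold`, `table` (per-region tier areas and
#'   percentages).
#' @export
classify_tiers <- function(suitability, threshold, sa_mask = NULL,
                           mangrove_mask = NULL, tidalflat_mask = NULL,
                           regions = NULL) {
  n <- ncell(suitability)
  getm <- function(m) {
    if (is.null(m)) return(rep(FALSE, n))
    v <- raster_values(m)
    stopifnot(length(v) == n)
    !is.na(v) & v != 0
  }
  suit <- raster_values(suitability)
  pot <- !is.na(suit) & suit > threshold
  sa <- getm(sa_mask); mg <- getm(mangrove_mask); tf <- getm(tidalflat_mask)
  tier <- integer(n)
  tier[pot] <- 2L                      # moderate by default (incl. tidal flat)
  tier[pot & mg] <- 1L                 # least
  tier[pot & sa] <- 3L                 # high wins over all masks
  area1 <- cell_area_hm2(suitability)
  all_regions <- c(list(`whole zone` = rep(TRUE, n)),
                   lapply(regions, getm))
  tab <- do.call(rbind, lapply(names(all_regions), function(nm) {
    inr <- all_regions[[nm]]
    a <- c(high = sum(tier == 3L & inr), moderate = sum(tier == 2L & inr),
           least = sum(tier == 1L & inr)) * area1
    s <- summarize_tier_areas(a["high"], a["moderate"], a["least"])
    data.frame(region = nm, high_hm2 = a[["high"]], high_pct = s$pct_high,
               moderate_hm2 = a[["moderate"]], moderate_pct = s$pct_moderate,
               least_hm2 = a[["least"]], least_pct = s$pct_least,
               total_hm2 = s$total)
  }))
  rownames(tab) <- NULL
  structure(list(tiers = raster_like(suitability, tier),
                 threshold = threshold, table = tab),
            class = "tier_map")
}

#' @export
print.tier_map <- function(x, ...) {
  cat(sprintf("<tier_map> threshold %.3f\n", x$threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Totals and within-region percentages of tier areas
#'
#' The arithmetic behind a potential-distribution summary row: total
#' potential area and the percentage of it in each tier, to 2 decimals.
#'
#' @param high,moderate,least tier areas (hm^2).
#' @return list `total`, `pct_high`, `pct_moderate`, `pct_least`.
#' @export
summarize_tier_areas <- function(high, moderate, least) {
  total <- high + moderate + least
  pct <- function(a) if (total > 0) round(100 * a / total, 2) else 0
  list(total = unname(total), pct_high = unname(pct(high)),
       pct_moderate = unname(pct(moderate)), pct_least = unname(pct(least)))
}
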