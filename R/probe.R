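# Site-leakage probe: a small two-hidden-layer classifier trained on
# frozen patch features to predict the acquisition site, under a
# patient-aware repeated train/test protocol.

#' Probe configuration
#'
#' Defaults follow the standard small-probe recipe for frozen embeddings:
#' two ReLU hidden layers of 500 and 200 units, 5 epochs of Adam with
#' batch size 60 on softmax (categorical) cross-entropy over integer site
#' labels, a 90/10 patient-aware split, 30 repeats. The output width is
#' set per run to the number of sites in scope.
#'
#' @param hidden integer vector of hidden-layer sizes (default `c(500, 200)`).
#' @param epochs training epochs (default 5).
#' @param batch_size minibatch size (default 60).
#' @param learning_rate Adam step size (default 1e-3, the optimizer's
#'   conventional default).
#' @param test_fraction held-out slide fraction (default 0.1).
#' @param n_repeats split/train/evaluate cycles (default 30).
#' @param seed integer seed; repeat `r` uses a seed derived from it.
#' @return list of class `probe_config`.
#' @export
probe_config <- function(hidden = c(500, 200), epochs = 5, batch_size = 60,
                         learning_rate = 1e-3, test_fraction = 0.1,
                         n_repeats = 30, seed = 1) {
  stopifnot(length(hidden) == 2, all(hidden >= 1), epochs >= 1,
            batch_size >= 1, test_fraction > 0, test_fraction < 1,
            n_repeats >= 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "probe_config")
}

#' Patient-aware train/test split
#'
#' Slides are split roughly `1 - test_fraction` / `test_fraction`, with two
#' guarantees: no patient appears in both sets, and every patient owning
#' more than one slide goes entirely to training (multi-slide patients in
#' the test set would let the probe match a patient, not a site). The
#' split is stratified by site so every in-scope site appears in the test
#' set when feasible; a site with fewer than two single-slide patients is
#' dropped from the test side with a warning.
#'
#' @param records manifest data.frame (`slide_id`, `patient_id`, plus a
#'   site label column).
#' @param test_fraction target test share of slides (default 0.1).
#' @param seed integer seed.
#' @param site_col column holding the site label (default `"institution"`).
#' @return Object of class `split_plan`: `train` and `test` slide-id
#'   vectors, `seed`, `repeat_index`.
#' @export
make_split <- function(records, test_fraction = 0.1, seed = 1,
                       site_col = "institution") {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("slide_id", "patient_id", site_col) %in% names(records)))
  slides_per_patient <- table(records$patient_id)
  multi <- names(slides_per_patient)[slides_per_patient > 1]
  singles <- records[!(records$patient_id %in% multi), , drop = FALSE]

  test_ids <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), records[[site_col]]),
                  function(rows) {
      site_singles <- intersect(rows,
                                which(!(records$patient_id %in% multi)))
      if (length(site_singles) < 2) {
        warning("site '", records[[site_col]][rows[1]],
                "' has < 2 single-slide patients; excluded from test set")
        return(character(0))
      }
      n_test <- max(1L, round(test_fraction * length(rows)))
      n_test <- min(n_test, length(site_singles) - 1L)
      records$slide_id[sample(site_singles, n_test)]
    }), use.names = FALSE)
  })
  if (length(test_ids) == 0) stop("no eligible test slides in any site")
  structure(list(train = setdiff(records$slide_id, test_ids),
                 test = test_ids, seed = seed, repeat_index = NA_integer_),
            class = "split_plan")
}

#' Train the site probe
#'
#' Fits the two-hidden-layer classifier of [probe_config()] on patch
#' features. Weight initialization and batch shuffling run on a private
#' seeded RNG stream, so refitting with the same seed reproduces the same
#' weights bit for bit.
#'
#' @param x `n_patches x d` feature matrix.
#' @param y site labels (factor or character), one per patch; at least two
#'   distinct classes.
#' @param config a [probe_config()].
#' @param seed integer seed (default derived from `config$seed`).
#' @return Object of class `site_probe` with `weights`, `classes`,
#'   `config`, `final_loss`.
#' @export
train_probe <- function(x, y, config = probe_config(),
                        seed = derive_seed(config$seed, 0)) {
  x <- as_feature_matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training data contains a single class")
  stopifnot(nrow(x) == length(y))
  w <- cpp_mlp_train(x, as.integer(y) - 1L, nlevels(y),
                     config$hidden[1], config$hidden[2],
                     config$epochs, config$batch_size,
                     config$learning_rate, seed)
  if (!is.finite(w$final_loss)) stop("training diverged: non-finite loss")
  structure(list(weights = w[c("W1", "b1", "W2", "b2", "W3", "b3")],
                 classes = levels(y), config = config,
                 final_loss = w$final_loss),
            class = "site_probe")
}

#' @export
predict.site_probe <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  w <- object$weights
  p <- cpp_mlp_predict(x, w$W1, as.numeric(w$b1), w$W2, as.numeric(w$b2),
                       w$W3, as.numeric(w$b3))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' Evaluate a fitted probe on held-out patches
#'
#' Reports patch-level accuracy and slide-level accuracy, where a slide's
#' predicted site is the majority vote over its patches (ties broken by
#' the highest mean class probability). Per-site precision, recall and F1
#' are one-vs-rest at slide level, alongside the slide-level confusion
#' matrix.
#'
#' @param probe a [train_probe()] fit.
#' @param x test feature matrix (`n_patches x d`).
#' @param y true site labels, one per patch.
#' @param slide_ids slide id per patch (groups patches into slides).
#' @return Object of class `probe_eval`: `patch_accuracy`,
#'   `slide_accuracy`, `per_site` (data.frame with precision/recall/F1 and
#'   test counts), `confusion`, `slide_predictions`.
#' @export
evaluate_probe <- function(probe, x, y, slide_ids) {
  x <- as_feature_matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) > 0, nrow(x) == length(y), length(y) == length(slide_ids))
  prob <- predict(probe, x, type = "prob")
  pred <- probe$classes[max.col(prob, ties.method = "first")]
  patch_acc <- mean(pred == y)

  slides <- unique(slide_ids)
  slide_pred <- vapply(slides, function(s) {
    rows <- slide_ids == s
    votes <- table(pred[rows])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    mean_prob <- colMeans(prob[rows, , drop = FALSE])
    top[which.max(mean_prob[top])]
  }, character(1))
  slide_true <- vapply(slides, function(s) y[slide_ids == s][1], character(1))
  slide_acc <- mean(slide_pred == slide_true)

  lev <- probe$classes
  confusion <- table(factor(slide_true, levels = lev),
                     factor(slide_pred, levels = lev),
                     dnn = c("true", "predicted"))
  per_site <- do.call(rbind, lapply(lev, function(s) {
    tp <- sum(slide_true == s & slide_pred == s)
    fp <- sum(slide_true != s & slide_pred == s)
    fn <- sum(slide_true == s & slide_pred != s)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(site = s, n_test_slides = tp + fn, precision = precision,
               recall = recall, f1 = f1, stringsAsFactors = FALSE)
  }))
  structure(list(patch_accuracy = patch_acc, slide_accuracy = slide_acc,
                 per_site = per_site, confusion = confusion,
                 slide_predictions = data.frame(slide_id = slides,
                                                true = slide_true,
                                                predicted = slide_pred,
                                                stringsAsFactors = FALSE)),
            class = "probe_eval")
}

# Stack per-slide feature matrices for the given slide ids; returns the
# matrix plus per-patch site labels and slide ids.
stack_features <- function(cohort, slide_ids, site_col = "institution") {
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "features")
  m <- cohort$manifest
  rows <- match(slide_ids, m$slide_id)
  stopifnot(!anyNA(rows))
  counts <- vapply(cohort$features[slide_ids], nrow, integer(1))
  list(x = do.call(rbind, cohort$features[slide_ids]),
       y = rep(m[[site_col]][rows], counts),
       slide = rep(slide_ids, counts))
}

#' Repeated patient-aware site-classification experiment
#'
#' Runs `n_repeats` full cycles (split, train, evaluate) with distinct
#' derived seeds on a feature-mode cohort, optionally restricted to a
#' contribution group or run per cancer project, and aggregates mean and
#' sd of patch- and slide-level accuracy plus mean per-site F1.
#'
#' @param cohort a feature-mode `site_cohort`.
#' @param config a [probe_config()].
#' @param scope `"all"`, `"groupA"`, `"groupB"` (contribution groups from
#'   [assign_groups()]), or `"per_project"` (one experiment per cancer
#'   project, sites restricted to that project).
#' @param threshold group-A contribution threshold (default 0.01).
#' @param site_col manifest column holding the site label.
#' @return For slide scopes, an object of class `probe_report`:
#'   `repeats` (per-repeat data.frame), `mean_patch_accuracy`,
#'   `sd_patch_accuracy`, `mean_slide_accuracy`, `sd_slide_accuracy`,
#'   `per_site_f1`, `scope`, `n_sites`. For `"per_project"`, a named list
#'   of such objects (projects with fewer than 2 sites are skipped with a
#'   message).
#' @export
repeat_experiment <- function(cohort, config = probe_config(),
                              scope = c("all", "groupA", "groupB",
                                        "per_project"),
                              threshold = 0.01, site_col = "institution") {
  stopifnot(inherits(cohort, "site_cohort"), cohort$mode == "features")
  scope <- match.arg(scope)
  m <- cohort$manifest

  if (scope == "per_project") {
    out <- list()
    for (proj in sort(unique(m$project))) {
      sub <- m[m$project == proj, , drop = FALSE]
      if (length(unique(sub[[site_col]])) < 2) {
        message("project ", proj, " has < 2 sites; skipped")
        next
      }
      out[[proj]] <- run_repeats(cohort, sub, config, site_col,
                                 scope = paste0("project:", proj))
    }
    if (length(out) == 0) stop("no project has >= 2 sites")
    return(out)
  }

  if (scope %in% c("groupA", "groupB")) {
    groups <- assign_groups(m, threshold = threshold)
    keep <- group_members(groups, sub("group", "", scope))
    m <- m[m[[site_col]] %in% keep, , drop = FALSE]
  }
  if (length(unique(m[[site_col]])) < 2)
    stop("scope '", scope, "' contains fewer than 2 sites")
  run_repeats(cohort, m, config, site_col, scope = scope)
}

run_repeats <- function(cohort, records, config, site_col, scope) {
  reps <- lapply(seq_len(config$n_repeats), function(r) {
    seed_r <- derive_seed(config$seed, r)
    plan <- suppressWarnings(
      make_split(records, config$test_fraction, seed = seed_r,
                 site_col = site_col))
    tr <- stack_features(cohort, plan$train, site_col)
    te <- stack_features(cohort, plan$test, site_col)
    probe <- train_probe(tr$x, factor(tr$y, levels = sort(unique(records[[site_col]]))),
                         config, seed = derive_seed(seed_r, 1))
    ev <- evaluate_probe(probe, te$x, te$y, te$slide)
    list(plan = plan, eval = ev)
  })
  patch <- vapply(reps, function(r) r$eval$patch_accuracy, numeric(1))
  slide <- vapply(reps, function(r) r$eval$slide_accuracy, numeric(1))
  f1_tabs <- lapply(reps, function(r) r$eval$per_site)
  all_sites <- sort(unique(unlist(lapply(f1_tabs, function(t) t$site))))
  f1 <- vapply(all_sites, function(s) {
    v <- unlist(lapply(f1_tabs, function(t) t$f1[t$site == s]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  structure(list(
    repeats = data.frame(repeat_index = seq_along(reps),
                         patch_accuracy = patch, slide_accuracy = slide),
    plans = lapply(reps, `[[`, "plan"),
    mean_patch_accuracy = mean(patch), sd_patch_accuracy = sd(patch),
    mean_slide_accuracy = mean(slide), sd_slide_accuracy = sd(slide),
    per_site_f1 = data.frame(site = all_sites, mean_f1 = unname(f1),
                             stringsAsFactors = FALSE),
    scope = scope, n_sites = length(all_sites),
    n_repeats = config$n_repeats),
    class = "probe_report")
}

#' @export
print.probe_report <- function(x, ...) {
  cat("<probe_report> scope ", x$scope, ": ", x$n_repeats, " repeats, ",
      x$n_sites, " sites\n", sep = "")
  cat(sprintf("  patch accuracy %.3f +/- %.3f; slide accuracy %.3f +/- %.3f\n",
              x$mean_patch_accuracy, x$sd_patch_accuracy,
              x$mean_slide_accuracy, x$sd_slide_accuracy))
  invisible(x)
}
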