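# Experiment orchestration: dataset construction (segments/beats ->
# spectrogram images + feature vectors, balanced and split), per-lead
# training, and fused evaluation producing a metrics row.

#' Pipeline run configuration
#'
#' @param kind `"rhythm"` (3-s windows, 9 features, STFT window 167) or
#'   `"beat"` (R-to-R excerpts, 11 features, STFT window 28).
#' @param mode Spectrogram encoding, `"gray"` or `"rgb"`.
#' @param img_height,img_width Rendered image size fed to the network.
#' @param train_frac Train fraction of the balanced set.
#' @param seed Master seed (balancing, splitting, training).
#' @param cache_dir Optional directory caching rendered items on disk.
#' @param map A [label_map()].
#' @param model Fitting configuration, a [fusion_config()]; its
#'   `n_handcrafted` and `input_mode` are aligned with `kind`/`mode`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(kind = c("rhythm", "beat"), mode = c("gray", "rgb"),
                       img_height = 32L, img_width = 32L, train_frac = 0.9,
                       seed = 1L, cache_dir = NULL, map = label_map(),
                       model = fusion_config()) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  model$input_mode <- mode
  model$n_handcrafted <- if (kind == "rhythm") 9L else 11L
  model$seed <- as.integer(seed)
  structure(list(kind = kind, mode = mode,
                 window_len = if (kind == "rhythm") 167L else 28L,
                 img_height = as.integer(img_height),
                 img_width = as.integer(img_width),
                 train_frac = train_frac, seed = as.integer(seed),
                 cache_dir = cache_dir, map = map, model = model),
            class = "run_config")
}

.render_item <- function(x, fs, cfg, key) {
  if (!is.null(cfg$cache_dir)) {
    f <- file.path(cfg$cache_dir, paste0(key, ".rds"))
    if (file.exists(f)) return(readRDS(f))
  }
  L <- min(cfg$window_len, length(x))
  img <- render_spectrogram(ecg_stft(x, L, max(1L, floor(L / 2)), fs = fs),
                            cfg$mode, cfg$img_height, cfg$img_width)$pixels
  if (!is.null(cfg$cache_dir)) {
    dir.create(cfg$cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(img, file.path(cfg$cache_dir, paste0(key, ".rds")))
  }
  img
}

#' Build a balanced, split, two-lead training dataset
#'
#' Extracts labeled items (3-s rhythm windows or heartbeats) from every
#' record, renders each item's spectrogram image and computes its
#' handcrafted feature vector on both leads, drops excluded beat types
#' (`map$beat_exclude`) for the heartbeat kind, balances classes by
#' undersampling and splits train/test with the class balance preserved.
#'
#' @param records List of [ecg_record()] objects.
#' @param cfg A [run_config()].
#' @return Object of class `ecg_dataset`: `train` / `test` (each with
#'   `images` and `features` per lead, plus `labels`) and a `manifest`
#'   data frame of per-class counts.
#' @export
build_dataset <- function(records, cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(records) == 0) stop("empty record source")
  items1 <- list(); items2 <- list(); labels <- c(); keys <- c()
  n_excluded <- 0L
  for (rec in records) {
    prec <- preprocess_record(rec)
    if (cfg$kind == "rhythm") {
      a <- slide_rhythm_windows(prec, 1, cfg$map)
      b <- slide_rhythm_windows(prec, 2, cfg$map)
    } else {
      a <- extract_heartbeats(prec, 1, cfg$map)
      b <- extract_heartbeats(prec, 2, cfg$map)
      ex <- vapply(a, function(x) x$symbol %in% cfg$map$beat_exclude,
                   logical(1))
      n_excluded <- n_excluded + sum(ex)
      a <- a[!ex]; b <- b[!ex]
    }
    items1 <- c(items1, a)
    items2 <- c(items2, b)
    labels <- c(labels, vapply(a, `[[`, integer(1), "label"))
    keys <- c(keys, vapply(a, function(x) {
      paste(x$record_id, cfg$kind, x$lead, x$start_sample, sep = "_")
    }, character(1)))
  }

  split <- balance_and_split(seq_along(labels), labels,
                             train_frac = cfg$train_frac, seed = cfg$seed)

  assemble <- function(ix) {
    nfeat <- if (cfg$kind == "rhythm") 9L else 11L
    per_lead <- function(items, lead_tag) {
      imgs <- vector("list", length(ix))
      feats <- matrix(0, length(ix), nfeat)
      for (j in seq_along(ix)) {
        it <- items[[ix[j]]]
        imgs[[j]] <- .render_item(it$samples, it$fs, cfg,
                                  paste(keys[ix[j]], lead_tag,
                                        cfg$img_height, cfg$img_width,
                                        cfg$mode, sep = "_"))
        feats[j, ] <- if (cfg$kind == "rhythm") rhythm_features(it)
                      else heartbeat_features(it)
      }
      colnames(feats) <- if (cfg$kind == "rhythm") rhythm_feature_names()
                         else heartbeat_feature_names()
      list(images = imgs, features = feats)
    }
    l1 <- per_lead(items1, "L1")
    l2 <- per_lead(items2, "L2")
    list(images = list(l1$images, l2$images),
         features = list(l1$features, l2$features),
         labels = labels[ix])
  }

  train <- assemble(split$train$idx)
  test <- assemble(split$test$idx)
  manifest <- data.frame(
    split = c("train", "train", "test", "test"),
    class = c(0, 1, 0, 1),
    count = c(sum(train$labels == 0), sum(train$labels == 1),
              sum(test$labels == 0), sum(test$labels == 1))
  )
  attr(manifest, "n_source_items") <- length(labels)
  attr(manifest, "n_excluded") <- n_excluded
  structure(list(kind = cfg$kind, cfg = cfg, train = train, test = test,
                 manifest = manifest),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("ECG %s dataset: %d train / %d test items (balanced)\n",
              x$kind, length(x$train$labels), length(x$test$labels)))
  print(x$manifest)
  invisible(x)
}

#' Train per-lead models and evaluate fused predictions
#'
#' Fits one feature-merging classifier per lead on the training split,
#' scores the test split per lead, fuses the scores, and reports the
#' confusion counts and metrics of the fused decision, in the style of a
#' results-table row.
#'
#' @param dataset An [build_dataset()] output.
#' @return List of class `ecg_experiment`: `models` (per lead), `counts`,
#'   `metrics`, `elapsed` (seconds, informational) and `manifest`.
#' @export
run_experiment <- function(dataset) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  cfg <- dataset$cfg
  t0 <- proc.time()[["elapsed"]]
  models <- lapply(1:2, function(ld) {
    mc <- cfg$model
    mc$seed <- cfg$model$seed + ld - 1L
    fusion_fit(dataset$train$images[[ld]], dataset$train$features[[ld]],
               dataset$train$labels, mc)
  })
  s1 <- predict(models[[1]], dataset$test$images[[1]],
                dataset$test$features[[1]], type = "score")
  s2 <- predict(models[[2]], dataset$test$images[[2]],
                dataset$test$features[[2]], type = "score")
  fused <- fuse_leads(s1, s2)
  counts <- confusion_counts(fused$label, dataset$test$labels)
  structure(list(models = models, counts = counts,
                 metrics = classification_metrics(counts),
                 elapsed = proc.time()[["elapsed"]] - t0,
                 manifest = dataset$manifest),
            class = "ecg_experiment")
}

#' @export
print.ecg_experiment <- function(x, ...) {
  c <- x$counts
  cat(sprintf("TP %d  FP %d  TN %d  FN %d | ", c$tp, c$fp, c$tn, c$fn))
  print(x$metrics)
  cat(sprintf("  (%.1f s)\n", x$elapsed))
  invisible(x)
}
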