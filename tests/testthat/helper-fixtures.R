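# Shared fixtures, built in code. Expensive objects are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small two-scanner in-memory cohort for unit tests
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    spec <- cohort_spec(n_cases = 3, roi_size = 96, seed = 100)
    profiles <- default_scanner_profiles()[c("philips", "3dhistech")]
    rois <- list()
    i <- 0L
    for (p in profiles) {
      for (k in 1:3) {
        i <- i + 1L
        rois[[i]] <- generate_roi(spec, p, seed = 100 + i,
                                  case_id = sprintf("%s_c%d", p$name, k),
                                  center_id = paste0("ctr_", p$name))
      }
    }
    rois
  })
}

# independent even-odd point-in-polygon oracle (brute force per pixel)
oracle_rasterize <- function(xs, ys, height, width, value) {
  mask <- matrix(0L, height, width)
  n <- length(xs)
  for (r in seq_len(height)) {
    py <- r - 0.5
    for (c in seq_len(width)) {
      px <- c - 0.5
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((ys[i] > py) != (ys[j] > py)) {
          xc <- xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j])
          if (px < xc) inside <- !inside
        }
        j <- i
      }
      if (inside) mask[r, c] <- value
    }
  }
  mask
}

# brute-force one-vs-rest F1 tally used as the scoring oracle
oracle_f1 <- function(pred, truth, code, ignore = 255L) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (truth[i] == ignore) next
    if (pred[i] == code && truth[i] == code) tp <- tp + 1L
    else if (pred[i] == code) fp <- fp + 1L
    else if (truth[i] == code) fn <- fn + 1L
  }
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# constant-score model: zero weights, chosen head biases -> per-channel
# constant sigmoid scores everywhere
constant_model <- function(biases, base_channels = 2L, patch_size = 128L,
                           normalize = FALSE) {
  K <- length(biases)
  params <- rep(0, rpcseg:::unet_nparams(base_channels, K))
  params[(length(params) - K + 1):length(params)] <- biases
  structure(list(params = params,
                 config = train_config(base_channels = base_channels,
                                       n_classes = K, normalize = normalize,
                                       augment = FALSE),
                 patch_size = as.integer(patch_size),
                 history = data.frame(epoch = 1L, train_loss = 0,
                                      val_loss = 0),
                 best_epoch = 1L),
            class = "trained_model")
}
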