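# Synthetic multichannel sensor recordings with class-dependent structure.
#
# Emulates body-sensor activity recordings: a piecewise-constant label
# sequence of activity bouts separated by null stretches; each body channel
# carries a class signature (offset + sinusoid, so temporal context matters
# and recurrent layers are exercised) plus white noise; quaternion and
# object/environment channels carry label-independent noise; missing values
# occur in runs, emulating wireless sensors dropping out.

#' Configuration for the synthetic sensor generator
#'
#' @param n_classes number of classes including the null class (class 0).
#' @param n_body,n_quaternion,n_object body / quaternion / object-environment
#'   channel counts.
#' @param T total timesteps.
#' @param bout_mean,bout_min mean and minimum activity-bout length
#'   (timesteps); null stretches use the same distribution.
#' @param noise_sd white-noise standard deviation added to every channel.
#' @param missing_rate per timestep-channel probability that a missing run
#'   starts.
#' @param missing_len mean missing-run length (geometric).
#' @param amp_range,offset_range ranges for per-class per-channel sinusoid
#'   amplitudes and offsets.
#' @param seed integer seed; the whole recording is deterministic given the
#'   config.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 5, n_body = 8, n_quaternion = 2,
                         n_object = 2, T = 6000, bout_mean = 60,
                         bout_min = 20, noise_sd = 0.1,
                         missing_rate = 0.001, missing_len = 10,
                         amp_range = c(0.5, 1.5), offset_range = c(-1, 1),
                         seed = 1L) {
  gn_assert(n_classes >= 2, "need >= 2 classes (null + at least one activity)")
  gn_assert(n_body >= 1, "need at least one body channel")
  gn_assert(n_quaternion >= 0 && n_object >= 0, "channel counts must be >= 0")
  gn_assert(T >= 1, "T must be >= 1")
  gn_assert(bout_min >= 1 && bout_mean >= bout_min, "invalid bout lengths")
  gn_assert(noise_sd >= 0, "noise_sd must be >= 0")
  gn_assert(missing_rate >= 0 && missing_rate <= 1, "invalid missing_rate")
  structure(list(n_classes = as.integer(n_classes),
                 n_body = as.integer(n_body),
                 n_quaternion = as.integer(n_quaternion),
                 n_object = as.integer(n_object), T = as.integer(T),
                 bout_mean = bout_mean, bout_min = bout_min,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 missing_len = missing_len, amp_range = amp_range,
                 offset_range = offset_range, seed = as.integer(seed)),
            class = "synth_config")
}

# Per-class per-body-channel signature parameters plus per-channel output
# scale/baseline, all deterministic in config$seed. Class 0 (null) has a
# flat zero signature so activities stand out against rest periods.
synth_params <- function(config) {
  with_seed(derive_seed(config$seed, "signature"), {
    K <- config$n_classes; Cb <- config$n_body
    offs <- matrix(stats::runif(K * Cb, config$offset_range[[1]],
                                config$offset_range[[2]]), K, Cb)
    amp <- matrix(stats::runif(K * Cb, config$amp_range[[1]],
                               config$amp_range[[2]]), K, Cb)
    freq <- matrix(stats::runif(K * Cb, 0.02, 0.2), K, Cb)   # cycles/timestep
    phase <- matrix(stats::runif(K * Cb, 0, 2 * pi), K, Cb)
    offs[1, ] <- 0; amp[1, ] <- 0                            # null class
    list(offset = offs, amp = amp, freq = freq, phase = phase,
         scale = stats::runif(Cb, 0.5, 2),
         base = stats::runif(Cb, -0.5, 0.5))
  })
}

# Piecewise-constant label sequence: null stretch, activity bout, null, ...
synth_labels <- function(config) {
  with_seed(derive_seed(config$seed, "labels"), {
    T <- config$T
    labs <- integer(0); seg_start <- integer(0); seg_class <- integer(0)
    pos <- 0L; active <- FALSE
    # activity classes are drawn from reshuffled cycles so every class
    # appears once the recording holds at least n_classes - 1 bouts
    pool <- integer(0)
    next_class <- function() {
      if (length(pool) == 0)
        pool <<- sample.int(config$n_classes - 1L)
      cls <- pool[[1]]
      pool <<- pool[-1]
      cls
    }
    while (pos < T) {
      len <- as.integer(min(max(config$bout_min,
                                stats::rpois(1, config$bout_mean)),
                            T - pos))
      cls <- if (active && config$n_classes > 1) next_class() else 0L
      seg_start <- c(seg_start, pos); seg_class <- c(seg_class, cls)
      labs <- c(labs, rep.int(cls, len))
      pos <- pos + len
      active <- !active
    }
    list(labels = labs,
         segments = data.frame(start = as.integer(seg_start),
                               end = as.integer(c(seg_start[-1], T) - 1L),
                               class = as.integer(seg_class)))
  })
}

#' Deterministic (noise-free) body-channel signal for a label sequence
#'
#' The class signature each body channel emits: per-channel baseline plus
#' scaled class offset and sinusoid. Used by tests to check the residual
#' noise level.
#'
#' @param config a [synth_config()].
#' @param labels integer label per timestep.
#' @return a `length(labels)` x `n_body` matrix.
#' @export
synth_ground_signal <- function(config, labels) {
  p <- synth_params(config)
  t <- seq_along(labels)
  k <- labels + 1L
  sig <- matrix(0, length(labels), config$n_body)
  for (c in seq_len(config$n_body)) {
    sig[, c] <- p$base[[c]] + p$scale[[c]] *
      (p$offset[k, c] + p$amp[k, c] *
         sin(2 * pi * p$freq[k, c] * t + p$phase[k, c]))
  }
  sig
}

#' Generate a synthetic sensor recording
#'
#' @param config a [synth_config()].
#' @return a list with `frame` (a [sensor_frame()] with role-tagged
#'   channels and missing runs) and `segments` (ground-truth bout table:
#'   `start`, `end` inclusive 0-based, `class`).
#' @export
generate_frame <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  L <- synth_labels(config)
  T <- config$T
  Cb <- config$n_body; Cq <- config$n_quaternion; Co <- config$n_object
  sig <- synth_ground_signal(config, L$labels)
  values <- with_seed(derive_seed(config$seed, "noise"), {
    v <- matrix(stats::rnorm(T * (Cb + Cq + Co), 0, config$noise_sd),
                T, Cb + Cq + Co)
    v[, seq_len(Cb)] <- v[, seq_len(Cb), drop = FALSE] + sig
    if (Cq + Co > 0) {
      # label-independent channels drift slowly so they are not constant
      for (c in (Cb + 1):(Cb + Cq + Co))
        v[, c] <- v[, c] + sin(2 * pi * (c - Cb) * seq_len(T) / T)
    }
    v
  })
  values <- with_seed(derive_seed(config$seed, "missing"), {
    if (config$missing_rate > 0) {
      C <- ncol(values)
      starts <- matrix(stats::runif(T * C) < config$missing_rate, T, C)
      for (c in seq_len(C)) {
        for (s in which(starts[, c])) {
          len <- 1L + stats::rgeom(1, 1 / config$missing_len)
          values[s:min(T, s + len - 1L), c] <- NA
        }
      }
    }
    values
  })
  roles <- c(rep("body", Cb), rep("quaternion", Cq), rep("object_env", Co))
  names_ <- c(sprintf("body%03d", seq_len(Cb)),
              if (Cq > 0) sprintf("quat%03d", seq_len(Cq)),
              if (Co > 0) sprintf("obj%03d", seq_len(Co)))
  schema <- channel_schema(c(names_, "label"), c(roles, "label"))
  list(frame = sensor_frame(values, L$labels, schema), segments = L$segments)
}

#' Body-sensor-network shaped fixture
#'
#' A recording with exactly 113 body, 16 quaternion and 119
#' object/environment channels plus the label column, 2400 timesteps and 18
#' classes (17 gestures + null) -- the channel layout the body-channel
#' filter expects from a full sensor-rich deployment.
#'
#' @param seed integer seed.
#' @return a [sensor_frame()].
#' @export
opportunity_like_fixture <- function(seed = 1L) {
  cfg <- synth_config(n_classes = 18, n_body = 113, n_quaternion = 16,
                      n_object = 119, T = 2400, bout_mean = 40,
                      bout_min = 15, noise_sd = 0.1, missing_rate = 5e-4,
                      seed = seed)
  generate_frame(cfg)$frame
}
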