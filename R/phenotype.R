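# Network-topology phenotype: construction, validation and the key=value
# text convention (B, w, wstep, f, eta, then per-layer ck/cs/cp/ca and
# dt/dn/dd/da/dr fields).

GN_ACTIVATIONS <- c("linear", "ReLU")
GN_DENSE_TYPES <- c("feedforward", "LSTM", "GRU")
GN_REGULARIZERS <- c("none", "L1", "L2")
GN_OPTIMIZERS <- c("SGD", "AdaGrad", "AdaDelta", "RMSProp", "Adam", "Adamax")

#' Specification of one convolutional layer
#'
#' @param kernels number of kernels (`ck`), >= 1.
#' @param kernel_size kernel length along the time axis (`cs`), >= 2.
#' @param pool max-pooling size (`cp`); 1 means no pooling.
#' @param activation `"linear"` or `"ReLU"` (`ca`).
#' @return a list of class `conv_layer_spec`.
#' @export
conv_layer_spec <- function(kernels, kernel_size, pool = 1L,
                            activation = "ReLU") {
  gn_assert(kernels >= 1, "conv layer needs kernels >= 1")
  gn_assert(kernel_size >= 2, "conv kernel size must be >= 2")
  gn_assert(pool >= 1, "pool size must be >= 1")
  gn_assert(activation %in% GN_ACTIVATIONS,
            sprintf("unknown activation '%s'", activation))
  structure(list(kernels = as.integer(kernels),
                 kernel_size = as.integer(kernel_size),
                 pool = as.integer(pool), activation = activation),
            class = "conv_layer_spec")
}

#' Specification of one dense (fully-connected or recurrent) layer
#'
#' @param type `"feedforward"`, `"LSTM"` or `"GRU"` (`dt`).
#' @param units hidden units (`dn`), >= 1.
#' @param dropout dropout fraction in `[0, 1)` (`dd`).
#' @param activation `"linear"` or `"ReLU"` (`da`).
#' @param regularizer `"none"`, `"L1"` or `"L2"` weight penalty (`dr`).
#' @return a list of class `dense_layer_spec`.
#' @export
dense_layer_spec <- function(type, units, dropout = 0,
                             activation = "linear", regularizer = "none") {
  gn_assert(type %in% GN_DENSE_TYPES, sprintf("unknown dense type '%s'", type))
  gn_assert(units >= 1, "dense layer needs units >= 1")
  gn_assert(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  gn_assert(activation %in% GN_ACTIVATIONS,
            sprintf("unknown activation '%s'", activation))
  gn_assert(regularizer %in% GN_REGULARIZERS,
            sprintf("unknown regularizer '%s'", regularizer))
  structure(list(type = type, units = as.integer(units), dropout = dropout,
                 activation = activation, regularizer = regularizer),
            class = "dense_layer_spec")
}

#' Full network-topology phenotype
#'
#' Bundles the input setup (batch size `B`, window size `w`, window step
#' `wstep`), the ordered convolutional and dense layer stacks, and the
#' learning setup (optimizer `f`, learning rate `eta`).
#'
#' @param batch_size minibatch size `B`.
#' @param window_size sliding-window length `w` in timesteps.
#' @param window_step sliding-window step `wstep` in timesteps.
#' @param conv_layers list of [conv_layer_spec()]s (>= 1).
#' @param dense_layers list of [dense_layer_spec()]s (>= 1).
#' @param optimizer learning rule, one of SGD, AdaGrad, AdaDelta, RMSProp,
#'   Adam, Adamax.
#' @param learning_rate positive learning rate `eta`.
#' @return an object of class `topology_spec`.
#' @export
topology_spec <- function(batch_size, window_size, window_step,
                          conv_layers, dense_layers,
                          optimizer = "Adam", learning_rate = 1e-3) {
  gn_assert(batch_size >= 1, "batch size must be >= 1")
  gn_assert(window_size >= 1, "window size must be >= 1")
  gn_assert(window_step >= 1, "window step must be >= 1")
  gn_assert(length(conv_layers) >= 1, "need at least one conv layer")
  gn_assert(length(dense_layers) >= 1, "need at least one dense layer")
  gn_assert(all(vapply(conv_layers, inherits, logical(1), "conv_layer_spec")),
            "conv_layers must be conv_layer_spec objects")
  gn_assert(all(vapply(dense_layers, inherits, logical(1), "dense_layer_spec")),
            "dense_layers must be dense_layer_spec objects")
  gn_assert(optimizer %in% GN_OPTIMIZERS,
            sprintf("unknown optimizer '%s'", optimizer))
  gn_assert(learning_rate > 0, "learning rate must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 conv_layers = conv_layers, dense_layers = dense_layers,
                 optimizer = optimizer, learning_rate = learning_rate),
            class = "topology_spec")
}

#' Number of convolutional / dense layers in a phenotype
#' @param spec a `topology_spec`.
#' @return integer layer count.
#' @export
n_conv <- function(spec) length(spec$conv_layers)

#' @rdname n_conv
#' @export
n_dense <- function(spec) length(spec$dense_layers)

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

#' Render a phenotype as key=value text
#'
#' Produces the conventional one-line description, e.g.
#' `"B=50 w=24 wstep=2 f=Adam eta=0.001 ck1=32 cs1=4 cp1=1 ca1=ReLU
#' dt1=LSTM dn1=512 dd1=0.5 da1=ReLU dr1=L2"`. The text parses back to an
#' equal spec with [parse_phenotype_text()].
#'
#' @param spec a `topology_spec`.
#' @return a character scalar.
#' @export
phenotype_to_text <- function(spec) {
  stopifnot(inherits(spec, "topology_spec"))
  parts <- c(sprintf("B=%d", spec$batch_size),
             sprintf("w=%d", spec$window_size),
             sprintf("wstep=%d", spec$window_step),
             sprintf("f=%s", spec$optimizer),
             sprintf("eta=%s", fmt_num(spec$learning_rate)))
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    parts <- c(parts, sprintf("ck%d=%d", i, cl$kernels),
               sprintf("cs%d=%d", i, cl$kernel_size),
               sprintf("cp%d=%d", i, cl$pool),
               sprintf("ca%d=%s", i, cl$activation))
  }
  for (i in seq_along(spec$dense_layers)) {
    dl <- spec$dense_layers[[i]]
    parts <- c(parts, sprintf("dt%d=%s", i, dl$type),
               sprintf("dn%d=%d", i, dl$units),
               sprintf("dd%d=%s", i, fmt_num(dl$dropout)),
               sprintf("da%d=%s", i, dl$activation),
               sprintf("dr%d=%s", i, dl$regularizer))
  }
  paste(parts, collapse = " ")
}

#' Parse key=value phenotype text back into a topology
#'
#' Inverse of [phenotype_to_text()]. Field order is free; layer indices
#' must be contiguous starting at 1.
#'
#' @param text a character scalar of `key=value` tokens.
#' @return a `topology_spec`.
#' @export
parse_phenotype_text <- function(text) {
  gn_assert(is.character(text) && length(text) == 1, "`text` must be a string")
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  kv <- regmatches(toks, regexec("^([A-Za-z]+[0-9]*)=(.+)$", toks))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad))
    gn_stop(sprintf("not a key=value token: '%s'", toks[bad][[1]]),
            "gennas_parse_error")
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- vapply(kv, `[[`, character(1), 3)
  names(vals) <- keys
  need <- function(k) {
    if (!k %in% keys) gn_stop(sprintf("missing field '%s'", k),
                              "gennas_parse_error")
    vals[[k]]
  }
  idx_of <- function(prefix) {
    hit <- grep(sprintf("^%s[0-9]+$", prefix), keys, value = TRUE)
    sort(as.integer(sub(prefix, "", hit)))
  }
  ci <- idx_of("ck"); di <- idx_of("dt")
  gn_assert(length(ci) >= 1 && identical(ci, seq_along(ci)),
            "conv layer indices must be contiguous from 1",
            "gennas_parse_error")
  gn_assert(length(di) >= 1 && identical(di, seq_along(di)),
            "dense layer indices must be contiguous from 1",
            "gennas_parse_error")
  conv <- lapply(ci, function(i)
    conv_layer_spec(as.integer(need(sprintf("ck%d", i))),
                    as.integer(need(sprintf("cs%d", i))),
                    as.integer(need(sprintf("cp%d", i))),
                    need(sprintf("ca%d", i))))
  dense <- lapply(di, function(i)
    dense_layer_spec(need(sprintf("dt%d", i)),
                     as.integer(need(sprintf("dn%d", i))),
                     as.numeric(need(sprintf("dd%d", i))),
                     need(sprintf("da%d", i)),
                     need(sprintf("dr%d", i))))
  topology_spec(as.integer(need("B")), as.integer(need("w")),
                as.integer(need("wstep")), conv, dense,
                need("f"), as.numeric(need("eta")))
}

#' Positional hyperparameter slots of a phenotype
#'
#' Flattens a topology into the ordered slot vector used by the niching
#' similarity: input setup (B, w, wstep), per-conv-layer fields in order,
#' per-dense-layer fields in order, then learning setup (f, eta).
#'
#' @param spec a `topology_spec`.
#' @return a character vector of slot values (named for inspection).
#' @export
phenotype_slots <- function(spec) {
  stopifnot(inherits(spec, "topology_spec"))
  out <- c(B = fmt_num(spec$batch_size), w = fmt_num(spec$window_size),
           wstep = fmt_num(spec$window_step))
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    v <- c(fmt_num(cl$kernels), fmt_num(cl$kernel_size), fmt_num(cl$pool),
           cl$activation)
    names(v) <- paste0(c("ck", "cs", "cp", "ca"), i)
    out <- c(out, v)
  }
  for (i in seq_along(spec$dense_layers)) {
    dl <- spec$dense_layers[[i]]
    v <- c(dl$type, fmt_num(dl$units), fmt_num(dl$dropout), dl$activation,
           dl$regularizer)
    names(v) <- paste0(c("dt", "dn", "dd", "da", "dr"), i)
    out <- c(out, v)
  }
  c(out, f = spec$optimizer, eta = fmt_num(spec$learning_rate))
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("<topology_spec> ", n_conv(x), " conv + ", n_dense(x), " dense\n  ",
      phenotype_to_text(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.topology_spec <- function(x, ...) phenotype_to_text(x)

#' Test two phenotypes for equality
#' @param a,b `topology_spec` objects.
#' @return logical.
#' @export
phenotype_equal <- function(a, b) {
  identical(phenotype_to_text(a), phenotype_to_text(b))
}
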