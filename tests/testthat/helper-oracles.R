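# Independent oracles and shared fixtures, built in code at test time.

# Weighted F1 from a contingency table -- an implementation path disjoint
# from weighted_f1()'s per-class counting loop.
oracle_weighted_f1 <- function(true, pred) {
  lv <- sort(unique(c(true, pred)))
  tab <- table(factor(true, levels = lv), factor(pred, levels = lv))
  tp <- diag(tab)
  prec <- ifelse(colSums(tab) > 0, tp / colSums(tab), 0)
  rec <- ifelse(rowSums(tab) > 0, tp / rowSums(tab), 0)
  w <- rowSums(tab) / length(true)
  s <- prec + rec
  2 * sum(w * ifelse(s > 0, prec * rec / s, 0))
}

# Similarity recomputed from the key=value phenotype text.
oracle_similarity <- function(sa, sb) {
  kv <- function(s) {
    toks <- strsplit(phenotype_to_text(s), " ")[[1]]
    v <- sub("^[^=]+=", "", toks)
    names(v) <- sub("=.*$", "", toks)
    v
  }
  va <- kv(sa); vb <- kv(sb)
  ncv <- function(v) sum(grepl("^ck", names(v)))
  ndv <- function(v) sum(grepl("^dt", names(v)))
  if (ncv(va) != ncv(vb) || ndv(va) != ndv(vb)) return(0)
  mean(va == vb[names(va)])
}

# Direct niching arithmetic: fa_i = fn_i * (1 - sum_{j!=i} sim_ij / (P-1))
oracle_adjust <- function(fns, sims) {
  P <- length(fns)
  vapply(seq_len(P), function(i)
    fns[[i]] * (1 - sum(sims[i, -i]) / (P - 1)), numeric(1))
}

# Recursive (non-stack) GE expansion for toy grammars: consumes codons at
# multi-alternative rules only, no wrapping.
oracle_expand <- function(grammar, codons) {
  pos <- 0L
  expand <- function(nt) {
    prods <- grammar$rules[[nt]]
    k <- length(prods)
    if (k > 1) {
      if (pos >= length(codons)) stop("exhausted", call. = FALSE)
      pos <<- pos + 1L
      p <- prods[[(codons[[pos]] %% k) + 1L]]
    } else p <- prods[[1]]
    paste(vapply(p, function(tk)
      if (tk$type == "nt") expand(tk$value) else tk$value, character(1)),
      collapse = "")
  }
  tryCatch(list(complete = TRUE, sentence = expand(grammar$start),
                used = pos),
           error = function(e) list(complete = FALSE, sentence = NA, used = pos))
}

# a small valid phenotype and variations
tiny_spec <- function(units = 8, type = "GRU", w = 24L, wstep = 2L,
                      B = 32L, eta = 0.01) {
  topology_spec(B, w, wstep,
                list(conv_layer_spec(8, 3, 2, "ReLU")),
                list(dense_layer_spec(type, units, 0, "linear", "none")),
                "Adam", eta)
}

# random complete individuals decoded from the shipped grammar
random_individuals <- function(n, grammar, codon_size = 256, capacity = 100) {
  out <- list()
  while (length(out) < n) {
    ch <- random_chromosome(codon_size, capacity)
    d <- decode_topology(ch, grammar)
    if (d$complete)
      out[[length(out) + 1]] <- list(chromosome = ch, derivation = d,
                                     fn = stats::runif(1), fa = NULL)
  }
  out
}

# Small separable windowed dataset, cached so several test files can share
# it without regenerating (the generator itself is tested separately).
.gn_test_cache <- new.env(parent = emptyenv())

separable_windows <- function(w = 24L, wstep = 2L) {
  key <- sprintf("sep.%d.%d", w, wstep)
  if (!exists(key, .gn_test_cache)) {
    cfg <- synth_config(n_classes = 3, n_body = 6, n_quaternion = 0,
                        n_object = 0, T = 3000, noise_sd = 0.1,
                        missing_rate = 0, seed = 99)
    fr <- generate_frame(cfg)$frame
    sp <- split_frame(fr, 0.6, 0.2)
    tr <- normalize_frame(interpolate_missing(filter_channels(sp$train)))
    va <- normalize_frame(interpolate_missing(filter_channels(sp$val)),
                          tr$stats, clip = TRUE)
    assign(key, list(train = slide_windows(tr, w, wstep),
                     val = slide_windows(va, w, wstep)), .gn_test_cache)
  }
  get(key, .gn_test_cache)
}
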