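# BNF parsing and the codon -> phenotype mapping

test_that("parse_grammar handles minimal, malformed and undefined-symbol input", {
  g <- parse_grammar("<a> ::= x | y")
  expect_length(g$rules, 1)
  expect_length(g$rules$a, 2)
  expect_identical(g$start, "a")

  expect_error(parse_grammar("a := x"), class = "gennas_parse_error")
  expect_error(parse_grammar("<a> ::= x <undefined>"),
               class = "gennas_validation_error")
})

test_that("shipped grammars parse and serialization is a fixed point", {
  for (which in c("default", "tiny")) {
    g <- read_grammar(default_grammar_path(which))
    expect_identical(g$start, "network")
    s1 <- serialize_grammar(g)
    s2 <- serialize_grammar(parse_grammar(s1))
    expect_identical(s1, s2)
  }
})

test_that("decode reproduces a hand-constructed two-conv-layer individual", {
  g <- read_grammar(default_grammar_path())
  # choice points in derivation order: B,w,wstep,f,eta, conv count,
  # 4 fields per conv layer, dense count, 5 fields per dense layer
  cod <- c(1, 2, 1, 4, 0,          # B=50 w=24 wstep=2 f=Adam eta=0.001
           1,                      # 2 conv layers
           2, 2, 0, 1,             # ck1=32 cs1=4 cp1=1 ca1=ReLU
           4, 0, 1, 1,             # ck2=128 cs2=2 cp2=2 ca2=ReLU
           0,                      # 1 dense layer
           1, 2, 2, 1, 2)          # LSTM 512 dd=0.5 ReLU L2
  d <- decode_topology(chromosome(c(cod, rep(0, 80))), g)
  expect_true(d$complete)
  expect_identical(
    phenotype_to_text(d$phenotype),
    paste("B=50 w=24 wstep=2 f=Adam eta=0.001",
          "ck1=32 cs1=4 cp1=1 ca1=ReLU ck2=128 cs2=2 cp2=2 ca2=ReLU",
          "dt1=LSTM dn1=512 dd1=0.5 da1=ReLU dr1=L2"))
  expect_identical(d$codons_used, 20L)
})

test_that("all-zero chromosome takes the first alternative everywhere", {
  g <- read_grammar(default_grammar_path())
  d <- decode_topology(chromosome(rep(0, 100)), g)
  expect_true(d$complete)
  sp <- d$phenotype
  expect_identical(sp$batch_size, 25L)
  expect_identical(sp$window_size, 8L)
  expect_identical(n_conv(sp), 1L)
  expect_identical(n_dense(sp), 1L)
  expect_identical(sp$conv_layers[[1]]$kernels, 8L)
  expect_identical(sp$optimizer, "SGD")
})

test_that("decode is deterministic and incomplete when codons run out", {
  g <- read_grammar(default_grammar_path())
  set.seed(10)
  ch <- random_chromosome(256, 100)
  expect_identical(ge_decode(ch, g), ge_decode(ch, g))
  short <- chromosome(c(0, 0), codon_size = 256, capacity = 100)
  d <- ge_decode(short, g)
  expect_false(d$complete)
  expect_true(is.na(d$sentence))
  expect_null(decode_topology(short, g)$phenotype)
})

test_that("decode matches recursive enumeration on a toy grammar", {
  g <- parse_grammar("<s> ::= a<x> | b\n<x> ::= c | d<s>")
  codon_size <- 3L
  for (len in 1:4) {
    grid <- do.call(expand.grid, rep(list(0:(codon_size - 1L)), len))
    for (r in seq_len(nrow(grid))) {
      cod <- as.integer(grid[r, ])
      mine <- ge_decode(chromosome(cod, codon_size, 10), g)
      ref <- oracle_expand(g, cod)
      expect_identical(mine$complete, ref$complete)
      if (ref$complete) {
        expect_identical(mine$sentence, ref$sentence)
        expect_identical(mine$codons_used, ref$used)
      }
    }
  }
})

test_that("mutating codons beyond codons_used never changes the phenotype", {
  g <- read_grammar(default_grammar_path())
  set.seed(123)
  checked <- 0L
  for (i in 1:200) {
    ch <- random_chromosome(256, 100)
    d <- decode_topology(ch, g)
    if (!d$complete || d$codons_used >= length(ch)) next
    ch2 <- as.integer(ch)
    tail_idx <- (d$codons_used + 1L):length(ch2)
    ch2[tail_idx] <- sample.int(256, length(tail_idx), replace = TRUE) - 1L
    d2 <- decode_topology(chromosome(ch2, 256, 100), g)
    expect_identical(phenotype_to_text(d$phenotype),
                     phenotype_to_text(d2$phenotype))
    checked <- checked + 1L
  }
  expect_gt(checked, 100)
})

test_that("complete phenotypes always satisfy the topology invariants", {
  g <- read_grammar(default_grammar_path())
  set.seed(7)
  for (i in 1:100) {
    d <- decode_topology(random_chromosome(256, 100), g)
    if (!d$complete) next
    sp <- d$phenotype
    expect_gte(n_conv(sp), 1L); expect_lte(n_conv(sp), 5L)
    expect_gte(n_dense(sp), 1L); expect_lte(n_dense(sp), 3L)
    for (cl in sp$conv_layers) {
      expect_gte(cl$kernels, 1L)
      expect_gte(cl$kernel_size, 2L)
      expect_gte(cl$pool, 1L)
    }
    for (dl in sp$dense_layers) {
      expect_gte(dl$units, 1L)
      expect_true(dl$dropout >= 0 && dl$dropout < 1)
    }
  }
})

test_that("random_chromosome is seeded, in range and uniform in mean", {
  c1 <- with(list(), { set.seed(5); random_chromosome(256, 100) })
  c2 <- with(list(), { set.seed(5); random_chromosome(256, 100) })
  expect_identical(c1, c2)

  set.seed(6)
  small <- random_chromosome(2, 10)
  expect_true(all(small %in% 0:1))
  expect_error(random_chromosome(1, 10), class = "gennas_argument_error")

  set.seed(7)
  draws <- as.integer(random_chromosome(256, 10000))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 127.5), 3 * se)
})

test_that("phenotype text round-trips and renders layers in order", {
  sp <- tiny_spec()
  expect_identical(phenotype_to_text(parse_phenotype_text(phenotype_to_text(sp))),
                   phenotype_to_text(sp))
  five <- topology_spec(50, 24, 2,
                        lapply(1:5, function(i) conv_layer_spec(8 * i, 2)),
                        list(dense_layer_spec("LSTM", 512)))
  txt <- phenotype_to_text(five)
  expect_identical(regmatches(txt, gregexpr("ck[0-9]", txt))[[1]],
                   paste0("ck", 1:5))
  expect_match(phenotype_to_text(
    topology_spec(50, 24, 2, list(conv_layer_spec(32, 4)),
                  list(dense_layer_spec("LSTM", 512)))),
    "ck1=32 cs1=4", fixed = TRUE)
})
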