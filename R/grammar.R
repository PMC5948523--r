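# BNF grammar parsing and grammatical-evolution genotype->phenotype mapping.
#
# A grammar is an ordered set of rules `<nt> ::= alt | alt`, one rule per
# line. Inside a production, anything of the form `<name>` is a nonterminal
# reference; every other character run is a terminal literal kept verbatim
# (including interior spaces), so the grammar fully controls the surface
# form of the generated sentence.

#' Parse a BNF grammar
#'
#' Reads a context-free grammar in Backus-Naur Form. Each rule occupies one
#' line, `<nonterminal> ::= alternative | alternative`; blank lines and
#' lines starting with `#` are ignored. The first rule's left-hand side is
#' the start symbol. Terminal literals are kept verbatim, so sentences are
#' assembled by plain concatenation of terminals.
#'
#' @param bnf_text character scalar (the grammar text) or a character vector
#'   of lines.
#' @return An object of class `ge_grammar`: a list with `rules` (named list;
#'   each element a list of productions, each production a list of tokens
#'   with `type` "nt"/"t" and `value`) and `start`.
#' @seealso [read_grammar()], [serialize_grammar()], [ge_decode()]
#' @export
#' @examples
#' g <- parse_grammar("<a> ::= x | y<b>\n<b> ::= z")
#' g$start
parse_grammar <- function(bnf_text) {
  gn_assert(is.character(bnf_text) && length(bnf_text) >= 1,
            "`bnf_text` must be character")
  lines <- unlist(strsplit(paste(bnf_text, collapse = "\n"), "\n", fixed = TRUE))
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*(#|$)", ln)) next
    m <- regmatches(ln, regexec("^\\s*<([^<>|]+)>\\s*::=(.*)$", ln))[[1]]
    if (length(m) == 0)
      gn_stop(sprintf("malformed BNF rule at line %d: %s", i, trimws(ln)),
              "gennas_parse_error")
    nt <- m[[2]]
    rhs <- m[[3]]
    alts <- strsplit(rhs, "|", fixed = TRUE)[[1]]
    if (length(alts) == 0 || all(trimws(alts) == ""))
      gn_stop(sprintf("rule <%s> has no productions (line %d)", nt, i),
              "gennas_parse_error")
    prods <- lapply(alts, function(a) tokenize_production(trimws(a)))
    if (!is.null(rules[[nt]]))
      gn_stop(sprintf("rule <%s> defined twice (line %d)", nt, i),
              "gennas_parse_error")
    rules[[nt]] <- prods
  }
  if (length(rules) == 0) gn_stop("grammar has no rules", "gennas_parse_error")
  g <- structure(list(rules = rules, start = names(rules)[[1]]),
                 class = "ge_grammar")
  validate_grammar(g)
  g
}

# Split one production into nt / terminal tokens. `<name>` is a nonterminal;
# everything between nonterminals is one verbatim terminal literal.
tokenize_production <- function(text) {
  if (nchar(text) == 0)
    gn_stop("empty production alternative", "gennas_parse_error")
  hits <- gregexpr("<[^<>|[:space:]]+>", text)[[1]]
  tokens <- list()
  pos <- 1L
  if (hits[[1]] != -1) {
    lens <- attr(hits, "match.length")
    for (k in seq_along(hits)) {
      if (hits[[k]] > pos)
        tokens[[length(tokens) + 1L]] <-
          list(type = "t", value = substr(text, pos, hits[[k]] - 1L))
      nt <- substr(text, hits[[k]] + 1L, hits[[k]] + lens[[k]] - 2L)
      tokens[[length(tokens) + 1L]] <- list(type = "nt", value = nt)
      pos <- hits[[k]] + lens[[k]]
    }
  }
  if (pos <= nchar(text))
    tokens[[length(tokens) + 1L]] <-
      list(type = "t", value = substr(text, pos, nchar(text)))
  tokens
}

validate_grammar <- function(g) {
  referenced <- unique(unlist(lapply(g$rules, function(prods)
    unlist(lapply(prods, function(p)
      vapply(Filter(function(tk) tk$type == "nt", p),
             function(tk) tk$value, character(1)))))))
  missing <- setdiff(referenced, names(g$rules))
  if (length(missing) > 0)
    gn_stop(sprintf("undefined nonterminal(s): %s",
                    paste0("<", missing, ">", collapse = ", ")),
            "gennas_validation_error")
  invisible(g)
}

#' Serialize a grammar back to BNF text
#'
#' The output parses back to an identical grammar (fixed point of
#' parse/serialize).
#'
#' @param grammar a `ge_grammar`.
#' @return a character scalar of BNF text.
#' @export
serialize_grammar <- function(grammar) {
  stopifnot(inherits(grammar, "ge_grammar"))
  lines <- vapply(names(grammar$rules), function(nt) {
    alts <- vapply(grammar$rules[[nt]], function(p)
      paste(vapply(p, function(tk)
        if (tk$type == "nt") paste0("<", tk$value, ">") else tk$value,
        character(1)), collapse = ""), character(1))
    paste0("<", nt, "> ::= ", paste(alts, collapse = " | "))
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Read a grammar from a file
#' @param path path to a BNF text file.
#' @return a `ge_grammar`.
#' @export
read_grammar <- function(path) {
  gn_assert(file.exists(path), sprintf("grammar file not found: %s", path))
  parse_grammar(readLines(path, warn = FALSE))
}

#' Path of the grammar shipped with the package
#'
#' `"default"` is the full network-topology grammar (batch size, window
#' setup, 1-5 convolutional layers, 1-3 dense layers, learning rule);
#' `"tiny"` is a reduced-domain variant for fast desk-scale runs.
#'
#' @param which `"default"` or `"tiny"`.
#' @return a file path.
#' @export
default_grammar_path <- function(which = c("default", "tiny")) {
  which <- match.arg(which)
  system.file("extdata",
              if (which == "default") "topology_grammar.bnf"
              else "topology_grammar_tiny.bnf",
              package = "gennas", mustWork = TRUE)
}

#' @export
print.ge_grammar <- function(x, ...) {
  cat("<ge_grammar> ", length(x$rules), " rules, start symbol <",
      x$start, ">\n", sep = "")
  invisible(x)
}

## ---- chromosomes -----------------------------------------------------------

#' Construct a chromosome of integer codons
#'
#' @param codons integer vector, each in `[0, codon_size)`.
#' @param codon_size exclusive upper bound on codon values (default 256).
#' @param capacity maximum chromosome length (default 100).
#' @return an object of class `ge_chromosome` (an integer vector with
#'   `codon_size` and `capacity` attributes).
#' @export
chromosome <- function(codons, codon_size = 256L, capacity = 100L) {
  gn_assert(is.numeric(codons) && all(codons == floor(codons)),
            "codons must be integers")
  codons <- as.integer(codons)
  gn_assert(codon_size >= 2, "`codon_size` must be >= 2")
  gn_assert(capacity >= 1, "`capacity` must be >= 1")
  gn_assert(length(codons) <= capacity, "chromosome longer than capacity")
  gn_assert(all(codons >= 0L & codons < codon_size),
            "codons must lie in [0, codon_size)")
  structure(codons, codon_size = as.integer(codon_size),
            capacity = as.integer(capacity), class = "ge_chromosome")
}

#' Draw a random chromosome
#'
#' Codons are drawn uniformly in `[0, codon_size)` from R's RNG stream
#' (seed with [set.seed()] for reproducibility).
#'
#' @inheritParams chromosome
#' @return a `ge_chromosome` of length `capacity`.
#' @export
random_chromosome <- function(codon_size = 256L, capacity = 100L) {
  gn_assert(codon_size >= 2, "`codon_size` must be >= 2")
  gn_assert(capacity >= 1, "`capacity` must be >= 1")
  chromosome(sample.int(codon_size, capacity, replace = TRUE) - 1L,
             codon_size, capacity)
}

#' @export
print.ge_chromosome <- function(x, ...) {
  cat("<ge_chromosome> length ", length(x), "/", attr(x, "capacity"),
      ", codon_size ", attr(x, "codon_size"), "\n", sep = "")
  invisible(x)
}

## ---- decoding --------------------------------------------------------------

#' Map a chromosome to a sentence of the grammar (GE decoding)
#'
#' Standard grammatical-evolution mapping: starting from the start symbol,
#' the left-most nonterminal is repeatedly expanded; when it has more than
#' one production the next codon selects the alternative via
#' `codon %% n_alternatives`. By default no codon is consumed at
#' single-alternative rules (`consume_single = FALSE`), maximizing the
#' effective use of the chromosome. There is no codon wrapping: a
#' derivation that exhausts the chromosome is returned as incomplete.
#'
#' @param chrom a `ge_chromosome` (or plain integer vector).
#' @param grammar a `ge_grammar`.
#' @param consume_single consume a codon even when a rule has a single
#'   alternative (off by default).
#' @param max_expansions safety cap on expansions, guarding against
#'   non-terminating recursive grammars.
#' @return An object of class `ge_derivation`: list with `complete`
#'   (logical), `codons_used`, `sentence` (character, `NA` if incomplete)
#'   and `tree`, a data frame with one row per expanded nonterminal
#'   (`symbol`, `n_alternatives`, `choice`, `codon`; `codon` is `NA` where
#'   no codon was consumed).
#' @export
#' @examples
#' g <- parse_grammar("<s> ::= a<x> | b\n<x> ::= 0 | 1")
#' ge_decode(chromosome(c(0, 1), codon_size = 4, capacity = 10), g)$sentence
ge_decode <- function(chrom, grammar, consume_single = FALSE,
                      max_expansions = 10000L) {
  stopifnot(inherits(grammar, "ge_grammar"))
  codons <- as.integer(chrom)
  rules <- grammar$rules
  # work stack of pending tokens (leftmost-first)
  stack <- list(list(type = "nt", value = grammar$start))
  out <- character(0)
  used <- 0L
  sym <- character(0); nalt <- integer(0); choice <- integer(0); cod <- integer(0)
  expansions <- 0L
  incomplete <- FALSE
  while (length(stack) > 0) {
    tk <- stack[[1]]
    stack <- stack[-1]
    if (tk$type == "t") {
      out[[length(out) + 1L]] <- tk$value
      next
    }
    expansions <- expansions + 1L
    if (expansions > max_expansions) { incomplete <- TRUE; break }
    prods <- rules[[tk$value]]
    k <- length(prods)
    if (k > 1 || consume_single) {
      if (used >= length(codons)) { incomplete <- TRUE; break }
      used <- used + 1L
      ch <- (codons[[used]] %% k) + 1L
      cval <- codons[[used]]
    } else {
      ch <- 1L
      cval <- NA_integer_
    }
    sym[[length(sym) + 1L]] <- tk$value
    nalt[[length(nalt) + 1L]] <- k
    choice[[length(choice) + 1L]] <- ch
    cod[[length(cod) + 1L]] <- cval
    stack <- c(prods[[ch]], stack)
  }
  structure(list(
    complete = !incomplete,
    codons_used = used,
    sentence = if (incomplete) NA_character_ else paste(out, collapse = ""),
    tree = data.frame(symbol = sym, n_alternatives = nalt,
                      choice = choice, codon = cod)
  ), class = "ge_derivation")
}

#' Decode a chromosome into a network topology
#'
#' Runs [ge_decode()] and, when the derivation is complete, parses the
#' generated sentence as a topology description (see
#' [parse_phenotype_text()]). Incomplete derivations carry a `NULL`
#' phenotype; downstream, such individuals receive fitness 0.
#'
#' @inheritParams ge_decode
#' @return a `ge_derivation` with an extra `phenotype` element
#'   (a [topology_spec()] or `NULL`).
#' @export
decode_topology <- function(chrom, grammar, consume_single = FALSE) {
  d <- ge_decode(chrom, grammar, consume_single = consume_single)
  d$phenotype <- if (d$complete) parse_phenotype_text(d$sentence) else NULL
  d
}

#' @export
print.ge_derivation <- function(x, ...) {
  if (x$complete)
    cat("<ge_derivation> complete, ", x$codons_used, " codons used\n  ",
        x$sentence, "\n", sep = "")
  else
    cat("<ge_derivation> INCOMPLETE after ", x$codons_used, " codons\n",
        sep = "")
  invisible(x)
}
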