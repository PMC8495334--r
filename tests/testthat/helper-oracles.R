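# Independent brute-force oracles and fixture helpers used across tests.
# These deliberately take different routes from the package code so that
# agreement is evidence, not tautology.

# Tryptic cut positions via a lookahead regex (package code walks the
# character vector instead).
oracle_cut_positions <- function(seq, proline_rule = TRUE) {
  pat <- if (proline_rule) "[KR](?!P)" else "[KR]"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# All tryptic peptides by enumerating boundary pairs directly.
oracle_digest <- function(seq, max_missed, min_len = 1L, max_len = 1000L,
                          proline_rule = TRUE) {
  n <- nchar(seq)
  bounds <- unique(c(0L, oracle_cut_positions(seq, proline_rule), n))
  bounds <- sort(bounds[bounds <= n])
  out <- list()
  nb <- length(bounds)
  for (a in 1:(nb - 1)) {
    for (b in (a + 1):nb) {
      missed <- b - a - 1L
      if (missed > max_missed) next
      s <- bounds[a] + 1L
      e <- bounds[b]
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <-
        data.frame(sequence = substr(seq, s, e), start = s, end = e,
                   missed_cleavages = missed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Random protein sequence over the 20 standard residues.
random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# Brute-force species-uniqueness dictionary built with nested loops over
# an environment (vs the package's split/aggregate route).
oracle_unique_keys <- function(peptides, equate_il) {
  dict <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(peptides))) {
    k <- toupper(peptides$sequence[i])
    if (equate_il) k <- gsub("[IL]", "J", k)
    cur <- if (exists(k, dict)) get(k, dict) else character(0)
    assign(k, union(cur, peptides$species[i]), dict)
  }
  keys <- ls(dict)
  keys[vapply(keys, function(k) length(get(k, dict)) == 1L, logical(1))]
}

# Marker-filter predicate applied by hand (mirrors the documented rules,
# not the implementation).
oracle_passes_filter <- function(row, min_len = 9, max_len = 17) {
  len <- nchar(row$sequence)
  len >= min_len && len <= max_len && row$missed_cleavages == 0 &&
    !grepl("M", row$sequence) && !grepl("[BJOUXZ]", row$sequence)
}
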