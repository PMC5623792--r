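# Naive, loop-based re-implementations used as independent oracles.
# They deliberately share no code with the package internals.

oracle_ud <- function(profile) {
  e <- profile_entries(profile)
  total <- sum(e$pct)
  acc <- 0
  for (i in seq_len(nrow(e))) {
    db <- e$double_bonds[i]
    if (db >= 1 && db <= 3) acc <- acc + db * e$pct[i]
  }
  acc / total
}

oracle_lc <- function(profile) {
  e <- profile_entries(profile)
  acc <- 0
  for (i in seq_len(nrow(e))) acc <- acc + e$carbons[i] * e$pct[i]
  acc / sum(e$pct)
}

oracle_cn <- function(profile, table) {
  e <- profile_entries(profile)
  acc <- 0
  for (i in seq_len(nrow(e))) {
    cn <- table$cn_me[table$label == e$label[i]]
    stopifnot(length(cn) == 1)
    acc <- acc + cn * e$pct[i]
  }
  acc / sum(e$pct)
}

# Brute-force substring scan for restriction sites (independent of the
# package's scanner); returns cut positions.
oracle_cuts <- function(seq, site, offset) {
  n <- nchar(seq); k <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(max(0, n - k + 1))) {
    if (substr(seq, i, i + k - 1) == site) cuts <- c(cuts, i - 1 + offset)
  }
  cuts[cuts > 0 & cuts < n]
}

random_profile <- function(n_acids = 10) {
  carbons <- sample(seq(12, 24, by = 2), n_acids, replace = TRUE)
  dbl <- vapply(carbons, function(cc) sample(0:min(4, cc %/% 2), 1), integer(1))
  labels <- unique(format_fa_label(carbons, dbl))
  pct <- runif(length(labels))
  fa_profile(setNames(100 * pct / sum(pct), labels))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

table5_profiles <- function(...) {
  read_fa_profiles(sco_extdata("table5_fatty_acids.csv"), ...)
}
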