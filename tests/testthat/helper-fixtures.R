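# shared helpers for building small fixtures in code

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# one-hot pattern matrix matching a residue string exactly
onehot_pattern <- function(residues) {
  one_hot_encode(residues)
}
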