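# shared fixtures for the test suite

# the published 64-nt minimal anti-EGFR aptamer sequence (bundled fixture)
GOL1 <- paste0("GCCGGCGGCATTTTGACGCCGCCGCCGGCCGGCTGCTTATGCTGCTCC",
               "GGGGGGCATATATGGC")

gol1_seq <- function() {
  read_fasta(system.file("extdata", "gol1.fasta", package = "aptamin"))[[1]]
}

rand_dna <- function(n, prob = c(.25, .25, .25, .25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# independent line-oriented re-read of the bundled parameter tables
bundled_par_lines <- function() {
  chunks <- sort(list.files(system.file("extdata", package = "aptamin"),
                            pattern = "^dna_mathews2004_dg", full.names = TRUE))
  unlist(lapply(chunks, readLines))
}

section_tokens <- function(lines, name) {
  start <- grep(paste0("^# ", name, "$"), lines)[1]
  stopifnot(!is.na(start))
  rest <- lines[(start + 1):length(lines)]
  end <- grep("^#", rest)[1]
  body <- rest[seq_len(end - 1)]
  body <- sub("/\\*.*$", "", body)
  toks <- unlist(strsplit(trimws(body), "[ \t]+"))
  toks[nzchar(toks)]
}

# random valid pseudoknot-free structure of length n (hairpins >= 3),
# built by recursive splitting; independent of the folding engine
rand_structure <- function(n) {
  pt <- integer(n)
  fill <- function(i, j) {
    while (i <= j) {
      if (j - i + 1 >= 5 && runif(1) < 0.6) {
        ks <- seq(i + 4, j)
        k <- ks[sample.int(length(ks), 1)]
        pt[i] <<- k; pt[k] <<- i
        fill(i + 1, k - 1)
        i <- k + 1
      } else {
        i <- i + 1
      }
    }
  }
  fill(1L, n)
  as_pair_table(pt)
}
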