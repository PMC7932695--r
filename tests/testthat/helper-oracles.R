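# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately use naive loops / enumeration, never
# the package's vectorized code paths.

# posterior responsibility by direct Bayes enumeration for one protein
bruteEStepProtein <- function(h, y) {
  lik <- numeric(length(h))
  for (j in seq_along(h)) lik[j] <- if (y == 1) h[j] else 1 - h[j]
  lik / sum(lik)
}

# marginal likelihood by explicit enumeration over all joint hidden
# assignments (one responsible IDR per protein)
bruteMarginalLogLik <- function(hByProtein, y, priorByProtein = NULL) {
  if (is.null(priorByProtein))
    priorByProtein <- lapply(hByProtein, function(h) rep(1 / length(h), length(h)))
  grid <- expand.grid(lapply(hByProtein, seq_along))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    p <- 1
    for (i in seq_along(hByProtein)) {
      j <- grid[g, i]
      h <- hByProtein[[i]][j]
      p <- p * priorByProtein[[i]][j] *
        (if (y[i] == 1) h else 1 - h)
    }
    total <- total + p
  }
  log(total)
}

# AUC by counting concordant pairs plus half the ties
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (if (p > n) 1 else if (p == n) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# tiny feature table with explicit coordinates: protein A has IDRs 1-45 and
# 50-90, protein B has one IDR 10-30
makeCoordTable <- function() {
  z <- matrix(c(1, 0, -1, 2, 0.5, 1.5), nrow = 3,
              dimnames = list(NULL, c("f1", "f2")))
  IdrFeatureTable(z, proteinId = c("A", "A", "B"),
                  start = c(1L, 50L, 10L), end = c(45L, 90L, 30L))
}

# feature table with chosen per-IDR probabilities under b = 1 (one feature)
# h values are turned into feature values via the logit
makeProbTable <- function(hByProtein) {
  prot <- rep(names(hByProtein), lengths(hByProtein))
  z <- matrix(qlogis(unlist(hByProtein)), ncol = 1,
              dimnames = list(NULL, "f1"))
  IdrFeatureTable(z, proteinId = prot)
}

# write a small feature/annotation table pair to temp files
writeTinyTables <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("tinytab")
    dir.create(dir)
  }
  ftxt <- c("idr_id\tf1\tf2",
            "A|1-45\t0.5\t-1",
            "A|50-90\t1.25\t0.25",
            "B|10-30\t-0.75\t2")
  atxt <- c("protein_id\tfun1\tfun2",
            "A\t1\t0",
            "B\t0\t1")
  fpath <- file.path(dir, "features.tsv")
  apath <- file.path(dir, "annotations.tsv")
  writeLines(ftxt, fpath)
  writeLines(atxt, apath)
  list(features = fpath, annotations = apath)
}

cox15Fasta <- function() {
  system.file("extdata", "cox15_idr_variants_dna.fa", package = "faidr")
}

cox15Proteins <- function() {
  dna <- Biostrings::readDNAStringSet(cox15Fasta())
  setNames(vapply(seq_along(dna),
                  function(i) as.character(translateDna(dna[[i]])), ""),
           sub(" .*", "", names(dna)))
}
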