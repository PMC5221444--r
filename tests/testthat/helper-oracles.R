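# Independent brute-force oracles. These deliberately share no code with
# the package: naive scanners, a term-by-term free-energy sum, and a plain
# dynamic-programming aligner, used only to cross-check results.

# term-by-term dG' = dG0' + RT * sum(nu_i * ln a_i), prime convention
oracle_delta_g <- function(rxn, cond) {
  R <- 8.314e-3
  total <- rxn$dg0_prime
  for (sp in names(rxn$stoichiometry)) {
    nu <- rxn$stoichiometry[[sp]]
    if (nu == 0) next
    a <- if (sp == "H2O") 1
    else if (sp == "H+") 10^(-cond$pH) / 1e-7
    else cond$activities[[sp]]
    total <- total + R * cond$temperature * nu * log(a)
  }
  total
}

# IUPAC base sets, written out independently of the package
.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T"))

oracle_compat <- function(x, y)
  length(intersect(.oracle_iupac[[x]], .oracle_iupac[[y]])) > 0

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# all-positions primer scan on both strands with the 3'-anchor rule
oracle_find_sites <- function(template, primer_seq, max_mm) {
  tpl <- strsplit(template, "")[[1]]
  scan <- function(pat_seq, strand, anchor_last) {
    pat <- strsplit(pat_seq, "")[[1]]
    hits <- NULL
    for (s in seq_len(length(tpl) - length(pat) + 1)) {
      mm <- 0
      for (k in seq_along(pat))
        if (!oracle_compat(pat[k], tpl[s + k - 1])) mm <- mm + 1
      anchor <- if (anchor_last) oracle_compat(pat[length(pat)],
                                               tpl[s + length(pat) - 1])
      else oracle_compat(pat[1], tpl[s])
      if (mm <= max_mm && anchor)
        hits <- rbind(hits, data.frame(start = s, strand = strand,
                                       mismatches = mm))
    }
    hits
  }
  out <- rbind(scan(primer_seq, "+", TRUE),
               scan(oracle_revcomp(primer_seq), "-", FALSE))
  if (is.null(out)) data.frame(start = integer(), strand = character(),
                               mismatches = integer())
  else out[order(out$start, out$strand), , drop = FALSE]
}

# all-positions restriction-site scan; returns sorted unique cut positions
oracle_digest_cuts <- function(sequence, enzymes) {
  tpl <- strsplit(sequence, "")[[1]]
  cuts <- integer()
  for (e in enzymes) {
    pat <- strsplit(e$recognition, "")[[1]]
    for (s in seq_len(length(tpl) - length(pat) + 1)) {
      ok <- TRUE
      for (k in seq_along(pat))
        if (!oracle_compat(pat[k], tpl[s + k - 1])) { ok <- FALSE; break }
      if (ok) cuts <- c(cuts, s - 1 + e$cut_offset)
    }
  }
  sort(unique(cuts[cuts > 0 & cuts < length(tpl)]))
}

oracle_digest <- function(sequence, enzymes) {
  cuts <- oracle_digest_cuts(sequence, enzymes)
  sort(diff(c(0, cuts, nchar(sequence))), decreasing = TRUE)
}

# ends-free (overlap) affine-gap alignment by explicit dynamic programming
# with traceback; returns percent identity over aligned columns.
# match 2, mismatch -1, gap of length L costs open + ext * L.
oracle_identity <- function(a, b, match = 2, mismatch = -1,
                            gap_open = 10, gap_ext = 4) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # A[i] aligned to B[j]
  X <- matrix(NEG, n + 1, m + 1)  # A[i] against a gap
  Y <- matrix(NEG, n + 1, m + 1)  # B[j] against a gap
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    prev <- if (i == 1 || j == 1) 0
    else max(M[i, j], X[i, j], Y[i, j])     # [i, j] holds (i-1, j-1)
    M[i + 1, j + 1] <- s + prev
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                           X[i, j + 1] - gap_ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                           Y[i + 1, j] - gap_ext)
  }
  # free trailing gaps: best M cell in last row or last column
  lastcol <- M[2:(n + 1), m + 1]; lastrow <- M[n + 1, 2:(m + 1)]
  if (max(lastcol) >= max(lastrow)) {
    i <- which.max(lastcol); j <- m
  } else {
    i <- n; j <- which.max(lastrow)
  }
  # traceback counting matches and columns
  state <- "M"; matches <- 0; cols <- 0
  while (i >= 1 && j >= 1) {
    if (state == "M") {
      cols <- cols + 1
      if (A[i] == B[j]) matches <- matches + 1
      if (i == 1 || j == 1) break
      s <- if (A[i] == B[j]) match else mismatch
      prev <- M[i + 1, j + 1] - s
      state <- if (abs(prev - M[i, j]) < 1e-9) "M"
      else if (abs(prev - X[i, j]) < 1e-9) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      cols <- cols + 1
      from_m <- abs(X[i + 1, j + 1] - (M[i, j + 1] - gap_open - gap_ext)) <
        1e-9
      state <- if (from_m) "M" else "X"
      i <- i - 1
    } else {
      cols <- cols + 1
      from_m <- abs(Y[i + 1, j + 1] - (M[i + 1, j] - gap_open - gap_ext)) <
        1e-9
      state <- if (from_m) "M" else "Y"
      j <- j - 1
    }
  }
  100 * matches / cols
}

# random helpers used across property tests
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_seq <- function(x, k, protect = integer()) {
  chars <- strsplit(x, "")[[1]]
  pool <- setdiff(seq_along(chars), protect)
  pos <- sample(pool, k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[p]), 1)
  paste(chars, collapse = "")
}

random_reaction <- function() {
  species <- c("propionate", "acetate", "HCO3-", "H2", "CH4", "H2O", "H+")
  k <- sample(2:6, 1)
  sp <- sample(species, k)
  coef <- sample(c(-2, -1.75, -1, -0.75, -0.5, 0.5, 0.75, 1, 1.5, 2), k,
                 replace = TRUE)
  reaction("random", stats::setNames(coef, sp),
           dg0_prime = round(runif(1, -150, 150), 1))
}

random_conditions <- function() {
  conditions(temperature = runif(1, 280, 340),
             activities = c(propionate = 10^runif(1, -4, 0),
                            acetate = 10^runif(1, -4, 0),
                            `HCO3-` = 10^runif(1, -3, 0),
                            H2 = 10^runif(1, -7, 0),
                            CH4 = 10^runif(1, -2, 0)),
             pH = runif(1, 5, 9))
}
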