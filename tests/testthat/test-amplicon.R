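primers <- std_primers()
enzymes <- std_enzymes()

test_that("an exact primer site is found at the right offset", {
  tpl <- paste0(strrep("T", 10), "GCTCAGTAACACGTGG", strrep("A", 10))
  hits <- find_primer_sites(tpl, primers$Met86f, max_mismatch = 0)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 26L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)
})

test_that("degenerate positions match each of their bases", {
  # E5F carries M (A or C) at position 12
  tpl <- paste0("AGAGTTTGATCATGGCT", strrep("G", 20), "AGAGTTTGATCCTGGCT")
  hits <- find_primer_sites(tpl, primers$E5F, max_mismatch = 0)
  hits <- hits[hits$strand == "+", ]
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$mismatches, c(0L, 0L))
})

test_that("the 3'-terminal base must match even within the mismatch budget", {
  site <- "GCTCAGTAACACGTGG"
  bad3 <- paste0(substr(site, 1, 15), "C")   # last base G -> C
  tpl <- paste0(strrep("T", 5), bad3, strrep("T", 5))
  expect_equal(nrow(find_primer_sites(tpl, primers$Met86f,
                                      max_mismatch = 1)), 0L)
  # the same single mismatch placed internally is tolerated
  badmid <- paste0(substr(site, 1, 7), "T", substr(site, 9, 16))
  tpl2 <- paste0(strrep("T", 5), badmid, strrep("T", 5))
  hits <- find_primer_sites(tpl2, primers$Met86f, max_mismatch = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 1L)
})

test_that("site discovery matches a naive all-positions scanner", {
  set.seed(21)
  prms <- c("AGAGTTTGATCMTGGCT", "GGANTCRC", "TTNACGY")
  for (i in 1:6) {
    tpl <- random_seq(800)
    prm <- sample(prms, 1)
    mm <- sample(0:2, 1)
    got <- find_primer_sites(tpl, prm, max_mismatch = mm)
    want <- oracle_find_sites(tpl, prm, mm)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("in-silico PCR recovers a constructed full-length product", {
  set.seed(5)
  core <- random_seq(1500 - 17 - 20)
  tpl <- paste0("AGAGTTTGATCATGGCT", core,
                oracle_revcomp("AAGGAGGTGATCCAACCACA"))
  amp <- simulate_pcr(tpl, primers$E5F, primers$E1541r,
                      bounds = c(200, 2000))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 1L)
  expect_equal(amp$end, 1500L)
  expect_equal(amp$strand, "+")
  expect_equal(nchar(amp$sequence), 1500L)

  # without the reverse site no product forms
  tpl2 <- paste0("AGAGTTTGATCATGGCT", core)
  expect_equal(nrow(simulate_pcr(tpl2, primers$E5F, primers$E1541r)), 0L)

  # the reverse complement template yields the mirrored minus-strand product
  rc <- oracle_revcomp(tpl)
  amp2 <- simulate_pcr(rc, primers$E5F, primers$E1541r,
                       bounds = c(200, 2000))
  expect_equal(nrow(amp2), 1L)
  expect_equal(amp2$strand, "-")
  expect_equal(c(amp2$start, amp2$end),
               c(nchar(rc) - amp$end + 1L, nchar(rc) - amp$start + 1L))
  expect_equal(amp2$sequence, amp$sequence)
})

test_that("length bounds gate PCR products", {
  core <- strrep("A", 100)
  tpl <- paste0("AGAGTTTGATCATGGCT", core,
                oracle_revcomp("AAGGAGGTGATCCAACCACA"))
  expect_equal(nrow(simulate_pcr(tpl, primers$E5F, primers$E1541r,
                                 bounds = c(200, 2000))), 0L)
  expect_equal(nrow(simulate_pcr(tpl, primers$E5F, primers$E1541r,
                                 bounds = c(50, 2000))), 1L)
})

test_that("a single recognition site splits a molecule at the cut offset", {
  expect_equal(digest("AAGCGCAA", enzymes$HhaI), c(5L, 3L))
  expect_equal(digest(strrep("A", 120), enzymes$HhaI), 120L)
})

test_that("a double digest unions the cuts of both enzymes", {
  seqn <- paste0(strrep("A", 40), "CCCGGG", strrep("T", 30), "CTCGAG",
                 strrep("A", 20))
  frags <- digest(seqn, list(enzymes$SmaI, enzymes$XhoI))
  expect_length(frags, 3L)
  expect_equal(sum(frags), nchar(seqn))
  expect_equal(frags, oracle_digest(seqn, list(enzymes$SmaI,
                                               enzymes$XhoI)))
})

test_that("digestion conserves length and matches the naive scanner", {
  set.seed(77)
  for (i in 1:5) {
    n <- sample(500:5000, 1)
    seqn <- random_seq(n)
    enz <- sample(enzymes, sample(1:3, 1))
    frags <- digest(seqn, enz)
    expect_equal(sum(frags), n)                         # conservation
    expect_equal(frags, oracle_digest(seqn, enz))       # oracle
  }
})

test_that("digests are strand symmetric up to the cut overhang", {
  set.seed(55)
  for (i in 1:4) {
    seqn <- random_seq(3000)
    # blunt cutters place the cut at the site centre: exact symmetry
    for (e in list(enzymes$SmaI, enzymes$HaeIII))
      expect_equal(digest(seqn, e), digest(oracle_revcomp(seqn), e))
    # sticky-end cutters shift each fragment end by at most the overhang
    for (e in list(enzymes$HhaI, enzymes$HinfI, enzymes$XhoI)) {
      a <- digest(seqn, e)
      b <- digest(oracle_revcomp(seqn), e)
      expect_length(b, length(a))
      expect_true(all(abs(a - b) <= nchar(e$recognition)))
    }
  }
})

test_that("fragments carry no residual sites across former cut points", {
  set.seed(13)
  seqn <- random_seq(3000)
  cuts <- oracle_digest_cuts(seqn, list(enzymes$HinfI))
  bounds <- cbind(c(1, cuts + 1), c(cuts, nchar(seqn)))
  for (k in seq_len(nrow(bounds))) {
    frag <- substr(seqn, bounds[k, 1], bounds[k, 2])
    expect_equal(digest(frag, enzymes$HinfI), nchar(frag))
  }
})

test_that("gel binning merges close bands and drops invisible fragments", {
  expect_equal(gel_bin(c(500, 502), tolerance = 0.05), 501L)
  expect_equal(gel_bin(c(500, 400), tolerance = 0.05), c(500L, 400L))
  expect_equal(gel_bin(c(30, 600), detection_limit = 50), 600L)
  expect_equal(gel_bin(integer()), integer())
})

test_that("clones group by identical fingerprints across all assays", {
  p <- function(clone, hha, hinf)
    list(clone = clone, patterns = list(HhaI = hha, HinfI = hinf))
  profs <- list(p("c1", c(300L, 200L), c(400L, 100L)),
                p("c2", c(300L, 200L), c(400L, 100L)),
                p("c3", c(300L, 200L), c(250L, 250L)))
  g <- group_profiles(profs)
  expect_length(g, 2L)
  expect_setequal(g[[1]]$members, c("c1", "c2"))
  expect_equal(g[[2]]$members, "c3")
  # permutation invariance of the partition
  g2 <- group_profiles(profs[c(3, 1, 2)])
  part <- function(x) sort(vapply(x, function(gr)
    paste(sort(gr$members), collapse = ","), ""))
  expect_identical(part(g), part(g2))
  # every clone lands in exactly one group
  expect_setequal(unlist(lapply(g, `[[`, "members")), c("c1", "c2", "c3"))
  # inconsistent assay lists are rejected
  bad <- list(p("c1", 300L, 100L),
              list(clone = "c2", patterns = list(HaeIII = 300L)))
  expect_error(group_profiles(bad), "same assay list")
})

test_that("ardra_profiles fingerprints whole clone sets", {
  set.seed(31)
  seqs <- c(a = random_seq(900), b = random_seq(900))
  seqs["c"] <- seqs["a"]
  profs <- ardra_profiles(seqs)
  expect_named(profs, c("a", "b", "c"))
  expect_named(profs$a$patterns, c("HhaI", "HinfI"))
  g <- group_profiles(profs)
  grp_of <- function(id) which(vapply(g, function(gr)
    id %in% gr$members, NA))
  expect_equal(grp_of("a"), grp_of("c"))
})
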