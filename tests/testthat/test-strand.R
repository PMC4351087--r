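# strand and mispair inference: the deterministic allele/orientation ->
# (polymerase, strand, template, primer) mapping

test_that("reversion mutations are the unique wild-type-restoring changes", {
  expect_equal(reversionMutation("G148T"), "TA->GC")
  expect_equal(reversionMutation("G148A"), "AT->GC")
  expect_equal(reversionMutation("A149G"), "GC->AT")
  expect_equal(reversionMutation("A149C"), "CG->AT")
  expect_error(reversionMutation("G149X"), "unknown allele")
})

test_that("candidate mispairs are the two strand-specific options", {
  cm <- candidateMispairs("G148T")
  keys <- sort(paste(cm$template, cm$primer, sep = "/"))
  expect_equal(keys, c("A/G", "T/C"))
  # identical-base alleles give identical-base mispairs
  cmC <- candidateMispairs("G148C")
  expect_setequal(paste(cmC$template, cmC$primer, sep = "/"), c("G/G", "C/C"))
  cmT <- candidateMispairs("A149T")
  expect_setequal(paste(cmT$template, cmT$primer, sep = "/"), c("A/A", "T/T"))
})

test_that("the two candidate mispairs are complementary images of each other", {
  # the same lesion seen from the other replication strand: template and
  # primer bases both complemented (A-G <-> T-C, C-T <-> G-A, ...)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  for (al in c("G148T", "A149C", "G148A", "A149G", "G148C", "A149T")) {
    cm <- candidateMispairs(al)
    expect_equal(unname(comp[cm$template[1]]), cm$template[2], label = al)
    expect_equal(unname(comp[cm$primer[1]]), cm$primer[2], label = al)
  }
})

test_that("assignMispair reproduces the published template/primer columns", {
  # golden 16-row table: every (allele, orientation, mutant polymerase)
  # combination of the four non-identical-base alleles
  golden <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
allele orientation polymerase template primer
G148T  F           epsilon    T        C
G148T  R           delta      T        C
G148T  F           delta      A        G
G148T  R           epsilon    A        G
A149C  F           epsilon    C        T
A149C  R           delta      C        T
A149C  F           delta      G        A
A149C  R           epsilon    G        A
G148A  F           epsilon    A        C
G148A  R           delta      A        C
G148A  F           delta      T        G
G148A  R           epsilon    T        G
A149G  F           epsilon    G        T
A149G  R           delta      G        T
A149G  F           delta      C        A
A149G  R           epsilon    C        A
")
  for (i in seq_len(nrow(golden))) {
    g <- StrainGenotype(golden$allele[i], golden$orientation[i],
                        pol2 = if (golden$polymerase[i] == "epsilon") "hom" else "wt",
                        pol3 = if (golden$polymerase[i] == "delta") "hom" else "wt")
    a <- assignMispair(g)
    lab <- paste(golden[i, 1:3], collapse = " ")
    expect_equal(a@templateBase, golden$template[i], label = lab)
    expect_equal(a@primerBase, golden$primer[i], label = lab)
    expect_equal(a@polymerase, golden$polymerase[i], label = lab)
    expect_equal(a@strand,
                 if (golden$polymerase[i] == "epsilon") "leading" else "lagging",
                 label = lab)
    expect_false(a@extrapolated)
  }
})

test_that("F and R assignments exhaust the two candidates for each polymerase", {
  for (al in c("G148T", "A149C", "G148A", "A149G")) {
    for (pol in c("epsilon", "delta")) {
      keys <- vapply(c("F", "R"), function(o) {
        g <- StrainGenotype(al, o,
                            pol2 = if (pol == "epsilon") "het" else "wt",
                            pol3 = if (pol == "delta") "het" else "wt")
        mispairKey(assignMispair(g))
      }, "")
      cand <- candidateMispairs(al)
      expect_setequal(unname(keys), paste(cand$template, cand$primer, sep = "/"))
    }
  }
})

test_that("assignment requires exactly one mutant polymerase; identical-base alleles flagged", {
  expect_error(assignMispair(StrainGenotype("G148T", "F")), "neither")
  expect_error(assignMispair(StrainGenotype("G148T", "F", pol2 = "hom", pol3 = "hom")),
               "both")
  a <- assignMispair(StrainGenotype("G148C", "F", pol3 = "hom"))
  expect_true(a@extrapolated)
})

test_that("equivalent-mispair pairing gives 8 cross-polymerase pairs", {
  pairs <- equivalentMispairPairs()
  expect_equal(nrow(pairs), 8L)
  # opposite orientations share the mispair
  expect_true(all(pairs$pol2_orientation != pairs$pol3_orientation))
  g148t_f <- pairs[pairs$allele == "G148T" & pairs$pol2_orientation == "F", ]
  expect_equal(paste(g148t_f$template, g148t_f$primer, sep = "/"), "T/C")
  expect_equal(g148t_f$pol3_orientation, "R")
  a149c <- pairs[pairs$allele == "A149C" & pairs$pol3_orientation == "F", ]
  expect_equal(paste(a149c$template, a149c$primer, sep = "/"), "G/A")
  expect_equal(a149c$pol2_orientation, "R")
})

test_that("assignment table covers the full grid and round-trips via TSV", {
  tab <- assignmentTable()
  expect_equal(nrow(tab), 6L * 2L * 2L)
  expect_true(all(tab$extrapolated == (tab$allele %in% c("G148C", "A149T"))))
  tmp <- tempfile(fileext = ".tsv")
  assignmentTable(file = tmp)
  back <- read.delim(tmp, stringsAsFactors = FALSE)
  expect_equal(back$template, tab$template)
  expect_equal(back$primer, tab$primer)
})
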