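test_that("mutation status matches a hand-tallied truth table", {
  # 30 records over 12 samples; qualifying classes are missense, nonsense,
  # any indel and splice site; silent and unknown classes never qualify
  maf <- data.frame(
    Tumor_Sample_Barcode = c(
      "s01", "s01", "s02", "s03", "s04", "s04", "s05", "s06", "s07",
      "s07", "s08", "s09", "s10", "s10", "s10", "s02", "s03", "s05",
      "s06", "s08", "s09", "s01", "s02", "s04", "s06", "s07", "s09",
      "s11", "s11", "s12"),
    Hugo_Symbol = c(
      "TP53", "KRAS", "TP53", "TP53", "TP53", "KRAS", "TP53", "TP53",
      "TP53", "TP53", "TP53", "TP53", "KRAS", "TP53", "TP53", "KRAS",
      "KRAS", "KRAS", "KRAS", "KRAS", "KRAS", "TP53", "TP53", "TP53",
      "TP53", "KRAS", "TP53", "TP53", "KRAS", "TP53"),
    Variant_Classification = c(
      "Missense_Mutation", "Silent", "Nonsense_Mutation", "Silent",
      "Frame_Shift_Del", "Missense_Mutation", "Splice_Site", "Silent",
      "In_Frame_Ins", "Silent", "Translation_Start_Site", "Silent",
      "Missense_Mutation", "Silent", "Silent", "Silent", "Silent",
      "Nonsense_Mutation", "3'UTR", "Frame_Shift_Ins", "Splice_Site",
      "Silent", "Silent", "Silent", "Intron", "Silent", "RNA",
      "Missense_Mutation", "Missense_Mutation", "Silent"),
    Variant_Type = "SNP", stringsAsFactors = FALSE)
  rec <- as_mutation_records(maf)
  samples <- sprintf("s%02d", 1:12)
  got <- mutation_status(rec, driver_event("TP53"), samples)
  # hand tally for TP53: s01 missense, s02 nonsense, s03 silent only,
  # s04 frameshift, s05 splice, s06 silent+intron, s07 inframe ins,
  # s08 unknown class, s09 silent+RNA, s10 silent only, s11 missense,
  # s12 silent
  expect_equal(unname(got),
               c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, TRUE, FALSE))
  got_k <- mutation_status(rec, driver_event("KRAS"), samples)
  expect_equal(unname(got_k),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE,
                 TRUE, TRUE, TRUE, FALSE))
  # sample absent from the records is wild type
  expect_false(mutation_status(rec, driver_event("TP53"), "s99")[["s99"]])
  # empty record set -> all wild type
  expect_true(all(!mutation_status(rec[0, ], driver_event("TP53"), samples)))
})

test_that("splice-site indels qualify and unknowns map to other", {
  maf <- data.frame(Tumor_Sample_Barcode = c("a", "b"),
                    Hugo_Symbol = "G1",
                    Variant_Classification = c("Splice_Site", "Weird_Thing"),
                    Variant_Type = c("DEL", "SNP"), stringsAsFactors = FALSE)
  rec <- as_mutation_records(maf)
  expect_equal(rec$variant_class, c("splice_site", "other"))
  expect_true(rec$is_indel[1])
  st <- mutation_status(rec, driver_event("G1"), c("a", "b"))
  expect_equal(unname(st), c(TRUE, FALSE))
  # an indel with an unknown classification still qualifies via is_indel
  maf2 <- data.frame(Tumor_Sample_Barcode = "c", Hugo_Symbol = "G1",
                     Variant_Classification = "Weird_Thing",
                     Variant_Type = "INS", stringsAsFactors = FALSE)
  expect_true(mutation_status(as_mutation_records(maf2),
                              driver_event("G1"), "c")[["c"]])
})

test_that("mutation status is monotone under record addition", {
  set.seed(31)
  samples <- sprintf("m%02d", 1:20)
  classes <- names(maf_class_table())
  maf <- data.frame(
    Tumor_Sample_Barcode = sample(samples, 40, replace = TRUE),
    Hugo_Symbol = "G",
    Variant_Classification = sample(classes, 40, replace = TRUE),
    Variant_Type = "SNP", stringsAsFactors = FALSE)
  ev <- driver_event("G")
  for (k in c(10, 20, 40)) {
    s_small <- mutation_status(as_mutation_records(maf[1:10, ]), ev, samples)
    s_big <- mutation_status(as_mutation_records(maf[1:k, ]), ev, samples)
    expect_true(all(s_big[s_small]))
  }
})

test_that("event eligibility applies q, frequency and census rules strictly", {
  elig <- data.frame(
    gene = c("A", "B", "C", "D"),
    q_significant_any_cancer = c(TRUE, TRUE, TRUE, FALSE),
    max_frequency = c(0.08, 0.05, 0.30, 0.40),
    in_census = c(TRUE, TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  events <- select_events(elig)
  expect_equal(vapply(events, `[[`, "", "gene"), "A")  # B: 0.05 not > 0.05
  expect_s3_class(events[[1]], "driver_event")
})

test_that("gain-of-function subsets via custom class filters", {
  maf <- data.frame(
    Tumor_Sample_Barcode = c("x", "y"), Hugo_Symbol = "NFE2L2",
    Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation"),
    Variant_Type = "SNP", stringsAsFactors = FALSE)
  gof <- driver_event("NFE2L2", name = "NFE2L2_GOF",
                      class_filter = function(r) r$variant_class == "missense",
                      subset_label = "GOF")
  st <- mutation_status(as_mutation_records(maf), gof, c("x", "y"))
  expect_equal(unname(st), c(TRUE, FALSE))
})

test_that("copy-number mapping: minimum rule, size filter, oracle equality", {
  mk_gene <- function(id, chrom, s, e) data.frame(
    gene_id = id, gene_name = id, chrom = chrom, start = s, end = e,
    strand = "+", biotypes = "protein_coding", mature_length = 1000,
    is_coding = TRUE, stringsAsFactors = FALSE)
  gene <- mk_gene("G1", "c1", 100000L, 120000L)

  seg <- data.frame(
    sample = c("s1", "s1", "s1"), chrom = "c1",
    start = c(90000L, 110000L, 115000L),
    end = c(115000L, 200000L, 124999L),
    amplitude = c(0.8, -0.3, -5), stringsAsFactors = FALSE)
  expect_warning(amp <- map_copy_number(seg, gene), "overlapping")
  expect_equal(amp["G1", "s1"], -0.3)   # min over the two >=10 kb segments

  small <- data.frame(sample = "s1", chrom = "c1", start = 110000L,
                      end = 119999L, amplitude = -9, stringsAsFactors = FALSE)
  expect_true(is.na(map_copy_number(small, gene)["G1", "s1"]))
  exact10k <- data.frame(sample = "s1", chrom = "c1", start = 110000L,
                         end = 120000L, amplitude = -9,
                         stringsAsFactors = FALSE)
  expect_equal(map_copy_number(exact10k, gene)["G1", "s1"], -9)

  # 50 random segments x 10 genes vs brute-force oracle
  set.seed(19)
  genes <- do.call(rbind, lapply(1:10, function(i) {
    s <- floor(runif(1, 0, 5e5))
    mk_gene(sprintf("g%02d", i), sample(c("c1", "c2"), 1), s,
            s + floor(runif(1, 2000, 40000)))
  }))
  class(genes) <- c("gene_models", "data.frame")
  segs <- data.frame(
    sample = sample(c("sa", "sb", "sc"), 50, replace = TRUE),
    chrom = sample(c("c1", "c2"), 50, replace = TRUE),
    start = floor(runif(50, 0, 5e5)), stringsAsFactors = FALSE)
  segs$end <- segs$start + floor(runif(50, 5000, 60000))
  segs$amplitude <- round(rnorm(50), 3)
  expect_warning(got <- map_copy_number(segs, genes), "overlapping")
  expect_equal(got, oracle_cn_map(segs, genes))

  # permutation invariance over segment order; shrinking min_segment
  # never removes an assigned amplitude
  perm <- segs[sample(nrow(segs)), ]
  expect_warning(got_p <- map_copy_number(perm, genes), "overlapping")
  expect_equal(got_p, got)
  suppressWarnings({
    wide <- map_copy_number(segs, genes, min_segment = 2000)
  })
  expect_true(all(!(is.na(wide) & !is.na(got))))
})

test_that("SEG reader converts 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tSegment_Mean",
               "s1\tc1\t1001\t2000\t0.5"), path)
  seg <- read_seg(path)
  expect_equal(seg$start, 1000L)
  expect_equal(seg$end, 2000L)
  expect_equal(seg$end - seg$start, 1000L)
})

test_that("centroid assignment: identity, noise, affine invariance, ties", {
  set.seed(41)
  genes <- sprintf("p%02d", 1:50)
  centroids <- matrix(rnorm(50 * 4, 5, 1), 50, 4,
                      dimnames = list(genes, c("LumA", "LumB", "Her2",
                                               "Basal")))
  expect_equal(unname(pam50_assign(centroids[, "LumB"], centroids)), "LumB")

  # noisy samples from centroid A assign correctly essentially always at
  # the generator's noise level (sd 0.5 vs profile sd 1 over 50 genes)
  hits <- replicate(200, {
    v <- centroids[, "Basal"] + rnorm(50, 0, 0.5)
    unname(pam50_assign(v, centroids)) == "Basal"
  })
  expect_gte(mean(hits), 0.99)

  v <- centroids[, "Her2"] + rnorm(50, 0, 0.5)
  expect_equal(unname(pam50_assign(3 * v + 10, centroids)),
               unname(pam50_assign(v, centroids)))

  # anti-correlated sample still gets the argmax label
  anti <- -centroids[, "LumA"]
  expect_false(is.na(pam50_assign(anti, centroids)))

  flat <- setNames(rep(1, 50), genes)
  expect_true(is.na(suppressWarnings(pam50_assign(flat, centroids))))

  dup <- centroids[, c(1, 1)]
  colnames(dup) <- c("first", "second")
  expect_warning(lab <- pam50_assign(centroids[, 1], dup), "tie")
  expect_equal(unname(lab), "first")
})

test_that("derived centroids are per-label mean log2 profiles", {
  set.seed(43)
  fp <- matrix(2^rnorm(20 * 6, 4), 20, 6,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  labels <- c("A", "A", "B", "B", "B", "A")
  ctr <- derive_centroids(fp, labels)
  expect_equal(ctr[, "A"], rowMeans(log2(fp[, c(1, 2, 6)] + 0.1)))
  expect_equal(ctr[, "B"], rowMeans(log2(fp[, 3:5] + 0.1)))
})
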