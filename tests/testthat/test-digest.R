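enz <- radseq_enzymes()

test_that("site scanning reports 0-based match positions", {
  s <- scan_sites("GAATTCAAGAATTC", enz$EcoRI)
  expect_equal(s$start, c(0L, 8L))
  expect_equal(s$enzyme, c("EcoRI", "EcoRI"))
  s2 <- scan_sites("GGACCTTGGTCC", enz$AvaII)
  expect_equal(s2$start, c(0L, 7L))
  expect_equal(nrow(scan_sites("AAAAAAAA", enz$EcoRI)), 0L)
})

test_that("ambiguous genome bases never match and case is ignored", {
  expect_equal(nrow(scan_sites("TTGAANTCTT", enz$EcoRI)), 0L)
  expect_equal(scan_sites("ttgaattctt", enz$EcoRI)$start, 2L)
})

test_that("site scanning agrees with a position-by-position IUPAC oracle", {
  set.seed(11)
  for (i in 1:5) {
    s <- random_dna(20000)
    for (e in enz) {
      expect_equal(scan_sites(s, e)$start, naive_scan(s, e$recognition))
    }
  }
})

test_that("reverse-complementing the genome mirrors the site positions", {
  set.seed(12)
  s <- random_dna(30000)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (e in enz) {
    fwd <- scan_sites(s, e)$start
    rev <- scan_sites(rc, e)$start
    expect_equal(sort(nchar(s) - e$site_length - fwd), sort(rev))
  }
})

test_that("a single digest yields one fragment per adjacent site pair", {
  s <- scan_sites("GAATTCAAGAATTCTTTTGAATTC", enz$EcoRI)
  fr <- build_fragments_single(s)
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$start, c(0L, 8L))
  expect_equal(fr$end, c(8L, 18L))
  expect_equal(fr$size, c(8L, 10L))
  expect_true(all(fr$left_enzyme == "EcoRI" & fr$right_enzyme == "EcoRI"))
  # a lone site leaves no sequencable fragment (terminal segments excluded)
  expect_equal(nrow(build_fragments_single(scan_sites("TTGAATTCTT",
                                                      enz$EcoRI))), 0L)
  expect_error(build_fragments_single(rbind(s, scan_sites("TCGA",
                                                          enz$TaqI))),
               "multiple enzymes")
})

test_that("single-digest fragment count is sites minus one per chromosome", {
  set.seed(13)
  seqs <- stats::setNames(vapply(1:3, function(i) random_dna(50000), ""),
                          c("a", "b", "c"))
  st <- scan_sites(seqs, enz$TaqI)
  fr <- build_fragments_single(st)
  per <- table(factor(fr$chrom, levels = names(seqs)))
  cnt <- table(factor(st$chrom, levels = names(seqs)))
  expect_equal(as.integer(per), pmax(as.integer(cnt) - 1L, 0L))
})

test_that("double digest keeps only fragments flanked by different enzymes", {
  sA <- data.frame(chrom = "c", start = c(0L, 220L), enzyme = "TaqI",
                   stringsAsFactors = FALSE)
  sB <- data.frame(chrom = "c", start = 500L, enzyme = "PstI",
                   stringsAsFactors = FALSE)
  fr <- build_fragments_double(sA, sB)
  # the TaqI-TaqI interval [0,220) is dropped; only [220,500) survives
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$start, 220L)
  expect_equal(fr$end, 500L)
  expect_equal(fr$left_enzyme, "TaqI")
  expect_equal(fr$right_enzyme, "PstI")
  # alternating sites give one fragment per change of enzyme
  sA2 <- data.frame(chrom = "c", start = c(0L, 450L), enzyme = "TaqI",
                    stringsAsFactors = FALSE)
  sB2 <- data.frame(chrom = "c", start = 300L, enzyme = "PstI",
                    stringsAsFactors = FALSE)
  fr2 <- build_fragments_double(sA2, sB2)
  expect_equal(nrow(fr2), 2L)
  expect_equal(fr2$left_enzyme, c("TaqI", "PstI"))
  expect_error(build_fragments_double(sA, sA), "distinct enzymes")
})

test_that("ddRADseq fragments match a brute-force consecutive-pair oracle", {
  set.seed(14)
  s <- random_dna(200000)
  sA <- scan_sites(s, enz$TaqI)
  sB <- scan_sites(s, enz$PstI)
  fr <- build_fragments_double(sA, sB)
  m <- rbind(as.data.frame(sA), as.data.frame(sB))
  m <- m[order(m$start), , drop = FALSE]
  ref <- list()
  for (i in seq_len(nrow(m) - 1)) {
    if (m$enzyme[i] != m$enzyme[i + 1]) {
      ref[[length(ref) + 1]] <- data.frame(
        start = m$start[i], end = m$start[i + 1],
        left = m$enzyme[i], right = m$enzyme[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  ref <- do.call(rbind, ref)
  expect_equal(fr$start, ref$start)
  expect_equal(fr$end, ref$end)
  expect_equal(fr$left_enzyme, ref$left)
  expect_equal(fr$right_enzyme, ref$right)
  expect_true(all(fr$left_enzyme != fr$right_enzyme))
})

test_that("size selection is inclusive at both bounds", {
  sizes <- c(150L, 199L, 200L, 350L, 500L, 501L)
  fr <- data.frame(chrom = "c", start = 0L, end = sizes,
                   left_enzyme = "TaqI", right_enzyme = "PstI",
                   size = sizes, stringsAsFactors = FALSE)
  kept <- size_select(fr, 200, 500)
  expect_equal(kept$size, c(200L, 350L, 500L))
  expect_equal(nrow(size_select(fr, 0, 1e9)), nrow(fr))
  expect_error(size_select(fr, 500, 200))
})

test_that("paired-end windows cover the first and last read-length bases", {
  fr <- data.frame(chrom = "c", start = 1000L, end = 1250L,
                   left_enzyme = "TaqI", right_enzyme = "PstI",
                   size = 250L, stringsAsFactors = FALSE)
  w <- make_windows(fr, 150)
  expect_equal(nrow(w), 2L)
  expect_equal(w$win_start, c(1000L, 1100L))
  expect_equal(w$win_end, c(1150L, 1250L))
  expect_equal(unique(w$fragment_id), "c:1000-1250")
  expect_setequal(w$read, 1:2)
  # a 300 bp fragment gives exactly abutting read windows
  fr$end <- 1300L; fr$size <- 300L
  w2 <- make_windows(fr, 150)
  expect_equal(w2$win_end[1], w2$win_start[2])
  # fragments shorter than the read length cannot be windowed
  fr$end <- 1100L; fr$size <- 100L
  expect_error(make_windows(fr, 150), "read_length")
})

test_that("fragment summaries aggregate densities per chromosome class", {
  g <- toy_genome(c(m1 = strrep("A", 1e6), m2 = strrep("A", 5e5),
                    z = strrep("A", 1e6)),
                  types = c("macro", "macro", "Z"))
  mk <- function(chrom, n, size) {
    data.frame(chrom = chrom, start = seq_len(n) * 1000L,
               end = seq_len(n) * 1000L + size,
               left_enzyme = "TaqI", right_enzyme = "PstI",
               size = size, stringsAsFactors = FALSE)
  }
  fr <- rbind(mk("m1", 10, 300L), mk("m2", 10, 300L), mk("z", 5, 300L),
              mk("m1", 3, 600L))  # 3 fragments outside the size window
  st <- fragment_stats(fr, g, 200, 500)
  expect_equal(st$per_chrom$n_fragments, c(10L, 10L, 5L))
  expect_equal(st$per_chrom$per_mb, c(10, 20, 5))
  macro <- st$per_type[st$per_type$type == "macro", ]
  expect_equal(macro$mean_per_mb, 15)
  expect_equal(macro$sd_per_mb, stats::sd(c(10, 20)))
  zrow <- st$per_type[st$per_type$type == "Z", ]
  expect_equal(zrow$sd_per_mb, 0)  # singleton class: nothing to vary
  expect_equal(st$overall$total_fragments, 28L)
  expect_equal(st$overall$in_window_fragments, 25L)
  expect_equal(st$overall$percent_in_window, 89.29)
})

test_that("percentages are rounded half-up at two decimals", {
  expect_equal(percent_of(1, 800), 0.13)   # 0.125 rounds up, not to even
  expect_equal(percent_of(1, 3), 33.33)
  expect_equal(percent_of(0, 5), 0)
  expect_equal(percent_of(5, 5), 100)
  expect_error(percent_of(1, 0))
})

test_that("the digest wrapper is consistent with its parts", {
  set.seed(15)
  g <- toy_genome(c(c1 = random_dna(80000), c2 = random_dna(40000)))
  d <- digest_genome(g, enz$TaqI, enz$PstI)
  expect_named(d$sites, c("TaqI", "PstI"))
  expect_equal(d$selected,
               size_select(d$fragments, 200, 500))
  expect_equal(d$windows, make_windows(d$selected, 150))
  expect_equal(d$stats$overall$total_fragments, nrow(d$fragments))
  expect_true(all(d$fragments$left_enzyme != d$fragments$right_enzyme))
})
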