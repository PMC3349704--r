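test_that("a query finds itself at full length and 100% identity", {
  set.seed(501)
  q <- sno_seq("q", random_seq(80))
  hits <- seeded_search(q, q)
  expect_true(length(hits) >= 1L)
  top <- hits[[1]]
  expect_equal(top$score, 80)
  expect_equal(top$query_interval, c(0L, 80L))
  expect_equal(top$subject$start, 0L)
  expect_equal(top$subject$end, 80L)
  expect_equal(top$identity_pct, 100)
})

test_that("minus-strand homologs score identically and map to forward coordinates", {
  set.seed(502)
  q <- sno_seq("q", random_seq(60))
  flank5 <- random_seq(100); flank3 <- random_seq(80)
  subj <- sno_seq("s", paste0(flank5, oracle_revcomp(q$seq), flank3))
  hits <- seeded_search(q, subj)
  minus <- Filter(function(h) h$subject$strand == "-", hits)
  expect_true(length(minus) >= 1L)
  expect_equal(minus[[1]]$score, 60)
  expect_equal(minus[[1]]$subject$start, 100L)
  expect_equal(minus[[1]]$subject$end, 160L)
})

test_that("seeded search recovers the Smith-Waterman optimum on homolog pairs", {
  set.seed(503)
  for (rep in 1:6) {
    q <- random_seq(70)
    qm <- strsplit(q, "")[[1]]
    nmut <- sample(3:10, 1)
    at <- sample(seq_along(qm), nmut)
    qm[at] <- vapply(qm[at], function(ch) sample(setdiff(c("A","C","G","T"), ch), 1), "")
    subj <- paste0(random_seq(150), paste(qm, collapse = ""), random_seq(180))
    hits <- seeded_search(sno_seq("q", q), sno_seq("s", subj),
                          sno_params(search.both_strands = FALSE))
    sw <- oracle_sw_score(q, subj)
    expect_true(length(hits) >= 1L)
    expect_equal(max(vapply(hits, function(h) h$score, numeric(1))), sw)
  }
})

test_that("word size 1 with unbounded windows degenerates to exact Smith-Waterman", {
  set.seed(504)
  params <- sno_params(search.word_size = 1L, search.xdrop = Inf,
                       search.min_score = 5, search.both_strands = FALSE)
  for (rep in 1:5) {
    q <- random_seq(60)
    s <- random_seq(150)
    hits <- seeded_search(sno_seq("q", q), sno_seq("s", s), params)
    sw <- oracle_sw_score(q, s)
    if (sw >= 5) {
      expect_equal(max(vapply(hits, function(h) h$score, numeric(1))), sw)
    } else {
      expect_length(hits, 0L)
    }
  }
})

test_that("lowering min_score or word size never loses hits", {
  set.seed(505)
  q <- sno_seq("q", random_seq(50))
  subj <- sno_seq("s", paste0(random_seq(120), q$seq, random_seq(120)))
  key <- function(h) sprintf("%s:%d-%d:%s", h$subject$contig, h$subject$start,
                             h$subject$end, h$subject$strand)
  base <- vapply(seeded_search(q, subj, sno_params(search.min_score = 20)),
                 key, character(1))
  lower <- vapply(seeded_search(q, subj, sno_params(search.min_score = 10)),
                  key, character(1))
  expect_true(all(base %in% lower))
  w3 <- vapply(seeded_search(q, subj, sno_params(search.word_size = 3L)),
               key, character(1))
  w2 <- vapply(seeded_search(q, subj, sno_params(search.word_size = 2L)),
               key, character(1))
  expect_true(all(w3 %in% w2))
})

test_that("global identity is symmetric, 100 on self, and matches enumeration", {
  set.seed(506)
  a <- sno_seq("a", random_seq(40))
  expect_equal(global_identity(a, a), 100)
  for (rep in 1:5) {
    x <- sno_seq("x", random_seq(sample(20:40, 1)))
    y <- sno_seq("y", random_seq(sample(20:40, 1)))
    expect_equal(global_identity(x, y), global_identity(y, x))
  }
  # prefixes align end-gap-free at 100%
  b <- sno_seq("b", substr(a$seq, 1, 25))
  expect_equal(global_identity(a, b), 100)
  # exhaustively enumerated optimum for two tiny sequences
  res <- oracle_overlap_identities("ACGT", "TGCA")
  got <- global_identity(sno_seq("p", "ACGT"), sno_seq("q", "TGCA"))
  expect_true(got %in% res$identities)
})

test_that("host-guided search stages intronic hits before the genome-wide pass", {
  set.seed(507)
  copy <- random_seq(60)
  exon <- function() random_seq(100)
  intron_bg <- function() random_seq(300)
  # host gene: 4 exons / 3 introns; copy implanted mid-intron 2 (0-based 1)
  i1 <- intron_bg()
  i2 <- paste0(random_seq(120), copy, random_seq(120))
  i3 <- intron_bg()
  contig_seq <- paste0(random_seq(200), exon(), i1, exon(), i2, exon(), i3,
                       exon(), random_seq(200))
  e1 <- 200L
  exons <- data.frame(
    start = c(e1, e1 + 100 + 300, e1 + 200 + 600, e1 + 300 + 900),
    end = c(e1 + 100, e1 + 200 + 300, e1 + 300 + 600, e1 + 400 + 900))
  host <- gene_model("hostG", "chrT", "+", exons)
  genome <- list(sno_seq("chrT", contig_seq))
  q <- sno_seq("q", copy)
  # a threshold chance alignments against 300-nt introns cannot reach
  strict <- sno_params(search.min_score = 40)

  hits <- host_guided_search(q, genome, list(host), "hostG", strict)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$stage, "host_introns")
  intron2 <- enumerate_introns(host)[2, ]
  expect_gte(hits[[1]]$subject$start, intron2$start)
  expect_lte(hits[[1]]$subject$end, intron2$end)
  # sequence recovered at the hit is the implanted copy
  expect_equal(substr(contig_seq, hits[[1]]$subject$start + 1,
                      hits[[1]]$subject$end), copy)

  # no intronic copy: the genome-wide stage takes over
  q2 <- sno_seq("q2", random_seq(60))
  contig2 <- sno_seq("chrT", paste0(contig_seq, random_seq(150), q2$seq,
                                    random_seq(150)))
  hits2 <- host_guided_search(q2, list(contig2), list(host), "hostG", strict)
  expect_length(hits2, 1L)
  expect_equal(hits2[[1]]$stage, "genome")

  # two copies in different introns are both reported by the extra-copy pass
  i1b <- paste0(random_seq(100), copy, random_seq(100))
  contig3_seq <- paste0(random_seq(200), exon(), i1b, exon(), i2, exon(), i3,
                        exon(), random_seq(200))
  hits3 <- host_guided_search(q, list(sno_seq("chrT", contig3_seq)),
                              list(host), "hostG", strict)
  expect_length(hits3, 2L)
  expect_true(all(vapply(hits3, function(h) h$score, numeric(1)) == 60))
  expect_true(all(vapply(hits3, function(h) h$stage, character(1)) == "host_introns"))

  # unknown host gene warns and falls through to the genome stage
  expect_warning(h4 <- host_guided_search(q, genome, list(host), "nosuch", strict),
                 "not found")
  expect_true(any(vapply(h4, function(h) h$stage, character(1)) == "genome"))
})
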