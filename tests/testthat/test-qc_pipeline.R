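write_fastq <- function(records) {
  fq <- tempfile(fileext = ".fastq")
  writeLines(unlist(lapply(records, function(r)
    c(paste0("@", r[[1]]), r[[2]], "+", r[[3]]))), fq)
  fq
}

test_that("read_qc applies the clean-read filters in order", {
  good <- "ACGTACGTACGTACGTACGTA"
  fq <- write_fastq(list(
    list("clean", good, strrep("I", 21)),
    list("lowq", good, paste0(strrep("I", 14), strrep("#", 7))),  # 33% < Q30
    list("nbase", "ACGTNNNGTACGTACGTACGT", strrep("I", 21)),      # 14% N
    list("polya", strrep("A", 21), strrep("I", 21)),
    list("short", "ACGTACGTACGTACG", strrep("I", 15)),
    list("long", strrep("ACGT", 8), strrep("I", 32))))
  res <- read_qc(fq)
  expect_equal(res$stats$input, 6L)
  expect_equal(res$stats$retained, 1L)
  expect_equal(res$reads$id, "clean")
  expect_equal(unname(res$stats$removed),
               c(1L, 1L, 1L, 2L))  # low_quality, n_bases, homopolymer, length
})

test_that("adapter trimming needs >= 6 nt overlap and rescues length", {
  adapter <- "AGATCGGAAGAGC"
  core <- "ACGTACGTACGTACGTACGTA"
  fq <- write_fastq(list(
    # full adapter inside the read
    list("full", paste0(core, adapter), strrep("I", 34)),
    # 7-nt terminal overlap with the adapter prefix
    list("part", paste0(core, substr(adapter, 1, 7)), strrep("I", 28)),
    # 5-nt overlap: below the threshold, read keeps its tail (length 26, kept)
    list("none", paste0(core, substr(adapter, 1, 5)), strrep("I", 26))))
  res <- read_qc(fq, qc_params(adapter = adapter))
  expect_equal(res$stats$adapter_trimmed, 2L)
  expect_equal(res$reads$sequence,
               c(core, core, paste0(core, substr(adapter, 1, 5))))
  # quality strings track the trimmed length
  expect_equal(nchar(res$reads$quality), nchar(res$reads$sequence))
})

test_that("read_qc rejects malformed FASTQ", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(read_qc(bad), class = "format_error")
})

test_that("composition_stats counts lengths and first bases", {
  out <- composition_stats(c("UGACAGAAGAGAGUGAGCACA", "UGACAGAAGAGAGUGAGCACC",
                             "AGACAGAAGAGAGUGAGCACG"))
  expect_equal(unname(out$length_histogram["21"]), 3L)
  expect_equal(out$first_base_matrix["21", "U"], 2L, ignore_attr = TRUE)
  expect_equal(out$first_base_matrix["21", "A"], 1L, ignore_attr = TRUE)
  expect_equal(rowSums(out$first_base_matrix),
               out$length_histogram, ignore_attr = TRUE)

  empty <- composition_stats(character(0))
  expect_equal(length(empty$length_histogram), 0L)

  out <- composition_stats(vapply(19:24, function(l)
    paste(rep("A", l), collapse = ""), character(1)))
  expect_equal(unname(out$length_histogram), rep(1L, 6))
})

test_that("precursor/stack/sample-sheet readers round-trip and validate", {
  d <- tempfile(); dir.create(d)
  hp <- make_hairpin(seed = 3)
  p <- hp$precursor
  write.table(data.frame(id = p$id, sequence = p$sequence,
                         structure = p$structure, mfe = p$mfe,
                         n_genome_hits = 1L),
              file.path(d, "prec.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  got <- read_precursors(file.path(d, "prec.tsv"))
  expect_equal(got[[1]]$sequence, p$sequence)
  expect_equal(got[[1]]$mfe, p$mfe)

  # FASTA + 3-line structure file form
  writeLines(c(">hp1 some description", gsub("U", "T", p$sequence)),
             file.path(d, "prec.fa"))
  writeLines(c(">hp1", p$structure, sprintf("mfe=%.4f", p$mfe)),
             file.path(d, "prec.str"))
  got2 <- read_precursors(file.path(d, "prec.fa"), file.path(d, "prec.str"))
  expect_equal(got2[[1]]$sequence, p$sequence)  # T converted back to U
  expect_equal(got2[[1]]$structure, p$structure)

  expect_error(read_precursors(file.path(d, "prec.fa"),
                               file.path(d, "prec.fa")),
               class = "format_error")

  st <- simulate_stack(hp, depth = 50, n_libraries = 2, seed = 1)
  write.table(cbind(precursor_id = "hp1", as.data.frame(st)),
              file.path(d, "stacks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stacks <- read_stacks(file.path(d, "stacks.tsv"))
  expect_equal(names(stacks), "hp1")
  expect_equal(sum(stacks$hp1$count), sum(st$count))
})

test_that("run_pipeline on the shipped fixture satisfies summary invariants", {
  fix <- system.file("extdata", "fixture", package = "mircurate")
  out <- tempfile()
  s <- run_pipeline(file.path(fix, "config.yaml"), out_dir = out, quiet = TRUE)
  expect_lte(s$n_very_high_confidence, s$n_high_confidence)
  expect_lte(s$n_high_confidence, s$n_candidates)
  expect_equal(s$n_conserved + s$n_novel, s$n_high_confidence)
  # planted truth is recovered
  truth <- jsonlite::read_json(file.path(fix, "truth.json"),
                               simplifyVector = TRUE)
  rep <- read.delim(file.path(out, "confidence_report.tsv"))
  expect_equal(rep$category[match(truth$id, rep$id)], truth$planted_category)
  cons <- read.delim(file.path(out, "conserved_novel.tsv"))
  planted_cons <- truth$id[truth$planted_conserved]
  expect_true(all(cons$status[match(planted_cons, cons$id)] == "conserved"))
  # every output the pipeline promises exists
  expect_true(all(file.exists(file.path(out,
    c("confidence_report.tsv", "conserved_novel.tsv", "isomirs.tsv",
      "counts.tsv", "tpm.tsv", "de_I_vs_Y.tsv", "de_M_vs_I.tsv",
      "de_M_vs_Y.tsv", "de_flags.tsv", "composition_length.tsv",
      "composition_first_base.tsv", "summary.json", "thresholds.yaml")))))
  # DE-flagged miRNAs are all in the HC set
  flags <- read.delim(file.path(out, "de_flags.tsv"))
  hc_ids <- rep$id[rep$category != "rejected"]
  expect_true(all(flags$id[flags$differentially_expressed] %in% hc_ids))
})

test_that("run_pipeline relaxing min_arm_exact_reads is monotone in VHC", {
  fix <- system.file("extdata", "fixture", package = "mircurate")
  cfg <- yaml::read_yaml(file.path(fix, "config.yaml"))
  for (k in c("precursors", "stacks", "sample_sheet", "known_matures"))
    cfg[[k]] <- file.path(fix, cfg[[k]])
  cfg$sample_sheet <- NULL  # skip DE for speed
  s10 <- run_pipeline(cfg, out_dir = tempfile(), quiet = TRUE)
  cfg$thresholds <- list(min_arm_exact_reads = 0)
  s0 <- run_pipeline(cfg, out_dir = tempfile(), quiet = TRUE)
  expect_gte(s0$n_very_high_confidence, s10$n_very_high_confidence)
})

test_that("run_pipeline validates its config before running", {
  expect_error(run_pipeline(list(), out_dir = tempfile()),
               class = "config_error")
  expect_error(run_pipeline(list(precursors = "/nonexistent.tsv",
                                 stacks = "/nonexistent.tsv"),
                            out_dir = tempfile()),
               class = "config_error")
})
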