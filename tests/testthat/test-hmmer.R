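# Engine-backed profile construction, screening and scoring on the shared
# synthetic fixture.

test_that("profiles built from gap-free alignments honour the column bound", {
  seqs <- tibble::tibble(uid = sprintf("t%d", 1:4),
                         residues = rep(strrep("ACDEFGHIKL", 5), 4))
  aln <- tempfile(fileext = ".afa")
  write_fasta(seqs, aln)  # identical 50-mers are a trivially valid alignment
  prof <- build_profile(aln, "toy50")
  expect_lte(prof$model_length, 50L)
  expect_true(file.exists(prof$hmm_path))
  # single-row and unreadable alignments are rejected
  one <- tempfile(fileext = ".afa")
  write_fasta(seqs[1, ], one)
  expect_error(build_profile(one, "solo"), "at least 2 rows")
  expect_error(build_profile(tempfile(), "missing"), "not found")
})

test_that("family profiles report their own members at the class threshold", {
  fx <- engine_fixture()
  class_c <- fx$registry[fx$registry$scope == "class" & fx$registry$class_label == "C", ]
  hits <- hmm_search(class_c$hmm_path, fx$faa, e_value = 1e-6)
  c_members <- fx$fam$uid[fx$fam$class_label == "C"]
  for (p in class_c$profile_id) {
    expect_true(all(c_members %in% hits$seq_id[hits$profile_id == p]))
  }
  expect_true(all(hits$seq_evalue <= 1e-6 | hits$dom_ievalue <= 1e-6))
})

test_that("the generic screen retains family members and rejects noise", {
  fx <- engine_fixture()
  # random 100-mers: no homology to the family
  noise <- gh9class:::with_seed(77, tibble::tibble(
    uid = sprintf("rnd%02d", 1:10),
    residues = replicate(10, paste(sample(c("A", "C", "D", "E", "G", "K", "L",
                                            "N", "P", "S", "T", "V"),
                                          100, replace = TRUE), collapse = ""))
  ))
  noise_faa <- tempfile(fileext = ".faa")
  write_fasta(noise, noise_faa)
  expect_length(screen_homologs(noise_faa, fx$registry), 0L)
  # family members all pass
  expect_setequal(screen_homologs(fx$faa, fx$registry), fx$fam$uid)
  # mixed proteome: exactly the family survives
  mixed_faa <- tempfile(fileext = ".faa")
  write_fasta(dplyr::bind_rows(fx$fam[, c("uid", "residues")], noise), mixed_faa)
  expect_setequal(screen_homologs(mixed_faa, fx$registry), fx$fam$uid)
  # empty proteome
  empty_faa <- tempfile(fileext = ".faa")
  writeLines(character(), empty_faa)
  expect_length(screen_homologs(empty_faa, fx$registry), 0L)
})

test_that("score tables are shaped by the registry and reproducible", {
  fx <- engine_fixture()
  sc1 <- score_profiles(fx$fam, fx$registry, search_config())
  profs <- fx$registry$profile_id[fx$registry$scope != "generic"]
  expect_identical(names(sc1), c("seq_id", profs))
  expect_identical(sc1$seq_id, fx$fam$uid)
  # determinism: identical table on a rerun
  sc2 <- score_profiles(fx$fam, fx$registry, search_config())
  expect_identical(sc1, sc2)
  # a sequence with no reported hit yields a missing cell: random noise
  noise <- tibble::tibble(uid = "noise1",
                          residues = strrep("ACDGKLNPSTVE", 30))
  sc3 <- score_profiles(dplyr::bind_rows(fx$fam[1, c("uid", "residues")], noise),
                        fx$registry, search_config())
  expect_true(all(is.na(unlist(sc3[sc3$seq_id == "noise1", -1]))))
})

test_that("best-region scoring picks the maximal domain score", {
  fx <- engine_fixture()
  # concatenating a member with itself yields two domains; the table cell must
  # equal the maximum single-domain score, not their sum
  member <- fx$fam[fx$fam$class_label == "B", ][1, ]
  doubled <- tibble::tibble(uid = "dup1",
                            residues = strrep(member$residues, 2))
  both <- dplyr::bind_rows(member[, c("uid", "residues")], doubled)
  faa <- tempfile(fileext = ".faa")
  write_fasta(both, faa)
  class_b <- fx$registry[fx$registry$scope == "class" &
                           fx$registry$class_label == "B", ][1, ]
  hits <- hmm_search(class_b$hmm_path, faa, e_value = 1e-6)
  dup_hits <- hits[hits$seq_id == "dup1", ]
  expect_gte(nrow(dup_hits), 2L)  # two regions reported
  sc <- score_profiles(both, fx$registry, search_config())
  expect_equal(sc[[class_b$profile_id]][sc$seq_id == "dup1"], max(dup_hits$dom_score))
  # full-sequence scoring is available behind the config switch and sums regions
  sc_full <- score_profiles(both, fx$registry,
                            search_config(score_kind = "full_sequence"))
  expect_gt(sc_full[[class_b$profile_id]][sc_full$seq_id == "dup1"],
            sc[[class_b$profile_id]][sc$seq_id == "dup1"])
})

test_that("leave-one-out class means pool the documented profile counts", {
  fx <- engine_fixture()  # n = (3, 3, 3): 14 retained profiles per target
  sc <- score_profiles(fx$fam, fx$registry, search_config())
  mem <- score_members(sc, fx$registry, mode = "loocv")
  expect_false(any(mem$unclassifiable))
  # cross-check one row by hand: target SYNA001 (class A)
  sel <- select_loocv(fx$registry, "SYNA001")
  expect_length(sel$retained_profile_ids, 14L)
  reg <- as.data.frame(fx$registry)
  row <- sc[sc$seq_id == "SYNA001", ]
  for (cl in c("A", "B", "C")) {
    ids_1d <- intersect(sel$retained_profile_ids,
                        reg$profile_id[reg$class_label == cl & reg$rep == "1D"])
    ids_3d <- intersect(sel$retained_profile_ids,
                        reg$profile_id[reg$class_label == cl & reg$rep == "3D"])
    expect_equal(mem[[paste0(tolower(cl), "_1d")]][mem$seq_id == "SYNA001"],
                 mean(unlist(row[, ids_1d])))
    expect_equal(mem[[paste0(tolower(cl), "_3d")]][mem$seq_id == "SYNA001"],
                 mean(unlist(row[, ids_3d])))
  }
  # generic mode means are the class-pair averages
  gen <- class_means(score_members(sc, fx$registry, mode = "generic"))
  expect_equal(gen$hmm_a, (gen$a_1d + gen$a_3d) / 2)
  # max-mean class recovers the planted architecture on the training family
  expect_equal(max_class(gen$hmm_a, gen$hmm_b, gen$hmm_c), fx$fam$class_label)
})
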