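# Molecule parsing, canonicalization, curation filters, scaffolds, table IO.

test_that("largest fragment is kept and descriptors populated", {
  rec <- parse_and_canonicalize(c("CCO.O", "c1ccccc1"))
  expect_identical(rec$canonical_smiles[1], canonicalize_smiles("CCO"))
  expect_equal(rec$heavy_atom_count, c(3L, 6L))
  expect_true(all(rec$mol_weight > 0))
  expect_true(all(rec$h_donors >= 0 & rec$h_acceptors >= 0 &
                    rec$rotatable_bonds >= 0))
})

test_that("unparseable SMILES signal an invalid-molecule condition", {
  err <- tryCatch(parse_and_canonicalize("not_a_smiles"),
                  error = function(e) e)
  expect_s3_class(err, "molfuse_invalid_molecule")
  expect_match(conditionMessage(err), "not_a_smiles")
})

test_that("canonicalization is idempotent", {
  smis <- small_library()$records$canonical_smiles[1:25]
  expect_identical(canonicalize_smiles(smis), smis)
})

test_that("drug-likeness filter keeps exactly the compliant records", {
  rec <- parse_and_canonicalize(c(
    "CCO",                                       # compliant
    "CCCCCCCCCCCCCC",                            # 11 rotatable bonds
    paste0("C", strrep("C", 49)),                # MW >> 600
    "OCC(O)C(O)C(O)C(O)C(O)C(O)C(O)CO"))         # > 5 H-bond donors
  expect_equal(rec$rotatable_bonds[2], 11L)
  kept <- drug_likeness_filter(rec)
  expect_identical(kept$canonical_smiles, rec$canonical_smiles[1])
  # every dropped record violates at least one printed threshold
  dropped <- rec[!rec$canonical_smiles %in% kept$canonical_smiles, ]
  viol <- dropped$mol_weight > 600 | dropped$h_donors > 5 |
    dropped$h_acceptors > 10 | dropped$rotatable_bonds > 10
  expect_true(all(viol))
  # order preservation and subset property on a mixed library
  lib <- small_library()$records
  keep <- drug_likeness_filter(lib)
  expect_true(all(keep$canonical_smiles %in% lib$canonical_smiles))
  expect_identical(keep$canonical_smiles,
                   lib$canonical_smiles[lib$canonical_smiles %in%
                                          keep$canonical_smiles])
  expect_identical(nrow(drug_likeness_filter(lib[0, ])), 0L)
})

test_that("Murcko scaffolds collapse substituents and ignore atom order", {
  ks <- scaffold_keys(c("Cc1ccccc1", "c1ccccc1", "CCO",
                        "Cc1ccc(O)cc1", "Nc1ccc(F)cc1",
                        "c1ccccc1C", "C[C@H](N)C(=O)O"))
  expect_identical(ks[1], ks[2])        # toluene -> benzene framework
  expect_identical(ks[4], ks[5])        # p-substituted pair -> same key
  expect_identical(ks[1], ks[6])        # input atom order irrelevant
  expect_identical(ks[3], "")           # acyclic -> empty key
  expect_identical(ks[7], "")
  # equivalence-relation sanity on a generated library: keys of identical
  # canonical SMILES are identical, and every cyclic molecule has a
  # non-empty key that itself maps to itself
  lib <- small_library()$records$canonical_smiles[1:12]
  k1 <- scaffold_keys(lib)
  expect_identical(scaffold_keys(lib), k1)
  cyc <- k1[nzchar(k1)]
  expect_identical(scaffold_keys(cyc), cyc)
})

test_that("dataset IO round-trips and drops bad rows with a count", {
  tab <- small_library()
  sub <- dataset_table(tab$records[1:10, ], tab$labels[1:10],
                       "classification", "roundtrip")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sub, path)
  back <- read_dataset(path)
  expect_identical(back$records$canonical_smiles,
                   sub$records$canonical_smiles)
  expect_equal(back$labels, sub$labels)
  expect_identical(back$task_kind, "classification")
  # one invalid row among 5
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,label", "CCO,1", "CCC,0", "xyz((,1", "c1ccccc1,0",
               "CCN,1"), bad)
  suppressMessages(tb <- read_dataset(bad))
  expect_equal(nrow(tb$records), 4L)
  expect_equal(tb$n_dropped, 1L)
})

test_that("GPCR-style curation: MW cutoff first, then minimum size", {
  tab <- small_library()
  heavy <- parse_and_canonicalize(paste0("C", strrep("C", 49)))
  # pad with molecules above the cutoff so the post-filter table is small
  rec <- rbind(tab$records[1:20, ], heavy[rep(1, 40), ])
  big <- dataset_table(rec, task_kind = "regression", name = "gpcr_demo")
  expect_warning(out <- curate_gpcr(big, mw_max = 600, min_rows = 50L),
                 "rejected")
  expect_null(out)
  ok <- curate_gpcr(big, mw_max = 600, min_rows = 10L)
  expect_true(all(ok$records$mol_weight <= 600))
  expect_equal(nrow(ok$records), 20L)
})
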