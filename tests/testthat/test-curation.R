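# The seven-step curation protocol, its audit report and the protonation
# variant.

test_that("inorganics are those without carbon", {
  recs <- records_of(c(rust = "[O-2].[O-2].[O-2].[Fe+3].[Fe+3]",
                       benzene = "c1ccccc1",
                       cyanide_salt = "CC[N+](CC)(CC)CC.[C-]#N"))
  out <- remove_inorganics(recs)
  ids <- vapply(out$records, `[[`, character(1), "id")
  expect_setequal(ids, c("benzene", "cyanide_salt"))
  expect_equal(out$entry$removed_ids, "rust")
})

test_that("mixtures keep exactly one organic component, stripped of counter-ions", {
  recs <- records_of(c(salt = "CC(=O)Oc1ccccc1C(=O)O.Cl",
                       two_organics = "c1ccccc1.Cc1ccccc1",
                       plain = "CCO"))
  out <- resolve_mixtures(recs)
  ids <- vapply(out$records, `[[`, character(1), "id")
  expect_setequal(ids, c("salt", "plain"))
  expect_equal(out$entry$removed_ids, "two_organics")
  salt <- out$records[[which(ids == "salt")]]
  expect_equal(qsarpipe:::mol_formula(salt$mol), "C9H8O4")  # aspirin, no HCl
  plain <- out$records[[which(ids == "plain")]]
  expect_equal(qsarpipe:::mol_formula(plain$mol), "C2H6O")  # untouched
})

test_that("organometallics and unsupported elements are removed", {
  recs <- records_of(c(hgme = "C[Hg]C", clbz = "Clc1ccccc1",
                       seleno = "C[Se]CCC(N)C(=O)O",
                       halogens = "BrCCl"))
  out <- remove_organometallics(recs)
  expect_equal(out$entry$removed_ids, "hgme")
  out2 <- remove_special_atoms(out$records)
  expect_equal(out2$entry$removed_ids, "seleno")
  ids <- vapply(out2$records, `[[`, character(1), "id")
  expect_setequal(ids, c("clbz", "halogens"))
})

test_that("standardization clears stereo, neutralizes and normalizes nitro", {
  # stereo SMILES and its flat form collapse to the same structure
  r <- records_of(c(chiral = "C[C@H](N)C(=O)O", flat = "CC(N)C(=O)O"))
  std <- lapply(r, standardize_record)
  expect_equal(qsarpipe:::mol_inchi(std)[1], qsarpipe:::mol_inchi(std)[2])

  carboxylate <- standardize_record(records_of(c(a = "CC(=O)[O-]"))[[1]])
  expect_equal(qsarpipe:::net_charge(carboxylate$mol), 0)
  expect_equal(sum(carboxylate$mol$atoms$nh[carboxylate$mol$atoms$elem == "O"]), 1)

  # charge-separated and pentavalent nitro converge
  nitros <- records_of(c(n1 = "O=[N+]([O-])c1ccccc1", n2 = "O=N(=O)c1ccccc1"))
  std <- lapply(nitros, standardize_record)
  expect_equal(qsarpipe:::mol_inchi(std)[1], qsarpipe:::mol_inchi(std)[2])
  expect_equal(qsarpipe:::net_charge(std[[2]]$mol), 0)

  # idempotence
  again <- standardize_record(std[[2]])
  expect_identical(again$mol$atoms, std[[2]]$mol$atoms)
})

test_that("duplicates with conflicting PCC are wholly removed, consistent ones collapse", {
  recs <- records_of(c(a = "c1ccccc1O", b = "Oc1ccccc1", c = "CCO"),
                     pcc = c(-0.40, -0.10, -0.20))
  out <- deduplicate(recs)
  ids <- vapply(out$records, `[[`, character(1), "id")
  expect_equal(ids, "c")
  expect_setequal(out$entry$removed_ids, c("a", "b"))

  recs2 <- records_of(c(a = "c1ccccc1O", b = "Oc1ccccc1", c = "CCO"),
                      pcc = c(-0.40, -0.40, -0.20))
  out2 <- deduplicate(recs2)
  ids2 <- vapply(out2$records, `[[`, character(1), "id")
  expect_equal(ids2, c("a", "c"))    # first occurrence kept

  distinct <- records_of(c(a = "CCO", b = "CCN"), pcc = c(-0.1, -0.2))
  expect_length(deduplicate(distinct)$records, 2)
})

test_that("permanent charges are removed but zwitterions with net zero stay", {
  recs <- lapply(records_of(c(tma = "C[N+](C)(C)C",
                              acid = "CC(=O)[O-]",
                              zwit = "C[N+](C)(C)CC(=O)[O-]")),
                 standardize_record)
  out <- remove_permanent_charges(recs)
  ids <- vapply(out$records, `[[`, character(1), "id")
  expect_setequal(ids, c("acid", "zwit"))
  expect_equal(out$entry$removed_ids, "tma")
})

test_that("protonation variant ionizes strong acids and bases only", {
  recs <- records_of(c(benzoic = "OC(=O)c1ccccc1",
                       propylamine = "CCCN",
                       acetanilide = "CC(=O)Nc1ccccc1",
                       aniline = "Nc1ccccc1",
                       sulfonic = "CS(=O)(=O)O",
                       guanidine = "NC(N)=N"))
  out <- assign_charge_states(recs)
  charges <- vapply(out, function(r) qsarpipe:::net_charge(r$mol), numeric(1))
  expect_equal(unname(charges), c(-1, 1, 0, 0, -1, 1))
})

test_that("the full protocol matches a hand-applied count on a dirty fixture", {
  # 22 records: 2 inorganic, 2 organic-pair mixtures, 1 salt, 2 organo-
  # metallic, 1 selenium, 1 permanent cation, 1 conflicting-PCC duplicate
  # pair (2 records), 11 clean.  Hand-applying the rules before coding:
  # 10 removals (2+2+2+1+1+2), the salt kept as its stripped parent, so
  # the 11 clean compounds plus the salt parent survive: 12.
  smis <- c(inorg1 = "OS(=O)(=O)O", inorg2 = "O=P(O)(O)O",
            mix1 = "c1ccccc1.Cc1ccccc1", mix2 = "CCO.CCCO",
            salt = "NCCc1ccccc1.Cl",
            met1 = "C[Hg]C", met2 = "C[Sn](C)(C)Cl",
            sel = "C[Se]C",
            cation = "C[N+](C)(C)C",
            dupA = "OCC(Br)(Cl)CO", dupB = "OCC(Br)(Cl)CO",
            c01 = "c1ccccc1", c02 = "CCO", c03 = "CC(=O)O",
            c04 = "Clc1ccccc1", c05 = "CCN", c06 = "c1ccncc1",
            c07 = "Brc1ccc(O)cc1", c08 = "CCS", c09 = "OCC(O)CO",
            c10 = "CC(C)C", c11 = "O=[N+]([O-])c1ccc(C)cc1")
  pcc <- rep(-0.1, length(smis))
  pcc[names(smis) == "dupB"] <- -0.5
  recs <- records_of(smis, pcc)
  out <- run_curation(recs)
  expect_length(out$dataset, 12)
  expect_false(any(c("dupA", "dupB") %in% dataset_ids(out$dataset)))
  expect_true("salt" %in% dataset_ids(out$dataset))
  rep_df <- as.data.frame(out$report)
  # count conservation: each step starts where the previous ended
  expect_equal(rep_df$input[-1], (rep_df$input - rep_df$removed)[-nrow(rep_df)])
  expect_equal(out$report$final, out$report$initial - sum(rep_df$removed))
})

test_that("curation is idempotent and empty input is legal", {
  smis <- c(a = "c1ccccc1O.[Na+].[Cl-]", b = "CC(=O)[O-]", c = "CCN")
  recs <- records_of(smis, pcc = c(-0.3, -0.2, 0.1))
  once <- run_curation(recs)
  twice <- run_curation(once$dataset$records)
  expect_equal(length(twice$dataset), length(once$dataset))
  expect_equal(sum(as.data.frame(twice$report)$removed), 0)
  expect_equal(qsarpipe:::mol_inchi(twice$dataset$records),
               qsarpipe:::mol_inchi(once$dataset$records))

  empty <- run_curation(list())
  expect_length(empty$dataset, 0)
  expect_equal(empty$report$final, 0)
})

test_that("step order protects metal counter-ion salts from the metal filter", {
  # sodium benzoate: step 2 strips Na+ before step 3 looks for metals
  recs <- records_of(c(nabz = "[Na+].[O-]C(=O)c1ccccc1"), pcc = -0.2)
  out <- run_curation(recs)
  expect_equal(dataset_ids(out$dataset), "nabz")
  mol <- out$dataset$records[[1]]$mol
  expect_false(any(mol$atoms$elem == "Na"))
  expect_equal(qsarpipe:::net_charge(mol), 0)   # neutralized carboxylic acid
})

test_that("neutral-variant output is charge-free and charged variant is not", {
  recs <- records_of(c(a = "OC(=O)c1ccccc1", b = "CCCN", c = "CCO"),
                     pcc = c(-0.3, -0.2, 0))
  neutral <- run_curation(recs, curation_config(charge_variant = "neutral"))
  expect_true(all(vapply(neutral$dataset$records,
                         function(r) qsarpipe:::net_charge(r$mol) == 0,
                         logical(1))))
  charged <- run_curation(recs, curation_config(charge_variant = "charged"))
  ch <- vapply(charged$dataset$records,
               function(r) qsarpipe:::net_charge(r$mol), numeric(1))
  expect_equal(sort(ch), c(-1, 0, 1))
})
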