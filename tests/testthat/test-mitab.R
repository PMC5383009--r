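# hand-built MITAB rows for parser fixtures
mk_row <- function(id_a, id_b, tax_a = "taxid:9606(human)",
                   tax_b = "taxid:9606(human)", ncol = 15L) {
  fields <- c(id_a, id_b, rep("-", 7L), tax_a, tax_b, rep("-", 4L))
  paste(fields[seq_len(ncol)], collapse = "\t")
}

write_fixture <- function(rows) {
  f <- tempfile(fileext = ".mitab")
  writeLines(c(paste(rep("#header", 15), collapse = "\t"), rows), f)
  f
}

test_that("parse_mitab extracts identifiers and taxa, keeps chemical rows, flags malformed rows", {
  f <- write_fixture(c(
    mk_row("uniprotkb:P05067", "uniprotkb:P02647"),
    mk_row("uniprotkb:P05067|intact:EBI-1", "chebi:\"CHEBI:15377\"",
           "taxid:9606(human)", "-")
  ))
  rec <- parse_mitab(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$id_a, c("uniprotkb:P05067", "uniprotkb:P05067"))
  expect_equal(rec$id_b[1L], "uniprotkb:P02647")
  # chemical-namespace row is retained at parse stage
  expect_equal(rec$id_b[2L], "chebi:\"CHEBI:15377\"")
  expect_equal(rec$taxon_a, c(9606L, 9606L))
  expect_true(is.na(rec$taxon_b[2L]))

  # empty file
  f0 <- write_fixture(character(0))
  expect_warning(rec0 <- parse_mitab(f0), "empty-input")
  expect_equal(nrow(rec0), 0L)

  # short row skipped and counted
  f_bad <- write_fixture(c(mk_row("uniprotkb:A", "uniprotkb:B"),
                           mk_row("uniprotkb:C", "uniprotkb:D", ncol = 10L)))
  expect_warning(rec_bad <- parse_mitab(f_bad), "malformed")
  expect_equal(nrow(rec_bad), 1L)
  expect_equal(attr(rec_bad, "malformed_rows"), 1L)
})

test_that("filter_records removes non-human (incl. mixed-taxon) and non-protein rows with exact tallies", {
  rows <- c(
    replicate(10, mk_row("uniprotkb:A1", "uniprotkb:B1")),
    replicate(3, mk_row("uniprotkb:M1", "uniprotkb:M2",
                        "taxid:10090(mouse)", "taxid:10090(mouse)")),
    replicate(2, mk_row("uniprotkb:A1", "chebi:\"CHEBI:1\""))
  )
  rec <- parse_mitab(write_fixture(rows))
  out <- filter_records(rec)
  expect_equal(nrow(out$records), 10L)
  expect_equal(out$report$rows_nonhuman_removed, 3L)
  expect_equal(out$report$rows_nonprotein_removed, 2L)

  # all-clean input is the identity
  clean <- parse_mitab(write_fixture(replicate(4, mk_row("uniprotkb:X", "uniprotkb:Y"))))
  expect_equal(nrow(filter_records(clean)$records), 4L)

  # human-mouse mixed row counts as non-human
  mixed <- parse_mitab(write_fixture(mk_row("uniprotkb:H", "uniprotkb:M",
                                            "taxid:9606(human)", "taxid:10090(mouse)")))
  outm <- filter_records(mixed)
  expect_equal(nrow(outm$records), 0L)
  expect_equal(outm$report$rows_nonhuman_removed, 1L)
})

test_that("dedupe_and_deloop canonicalizes swapped pairs, strips self-loops and isoform suffixes", {
  rows <- c(mk_row("uniprotkb:A", "uniprotkb:B"),
            mk_row("uniprotkb:B", "uniprotkb:A"),
            mk_row("uniprotkb:A", "uniprotkb:A"),
            mk_row("uniprotkb:A", "uniprotkb:B"))
  rec <- filter_records(parse_mitab(write_fixture(rows)))$records
  out <- dedupe_and_deloop(rec)
  expect_equal(unname(out$edges), cbind("A", "B"))
  expect_equal(out$report$selfloops_removed, 1L)
  expect_equal(out$report$duplicates_removed, 2L)

  # already-simple input is the identity
  rec2 <- filter_records(parse_mitab(write_fixture(c(
    mk_row("uniprotkb:A", "uniprotkb:B"), mk_row("uniprotkb:B", "uniprotkb:C")))))$records
  out2 <- dedupe_and_deloop(rec2)
  expect_equal(nrow(out2$edges), 2L)
  expect_equal(out2$report$duplicates_removed, 0L)

  # isoform collapses to parent (and creates a self-loop here)
  rec3 <- filter_records(parse_mitab(write_fixture(
    mk_row("uniprotkb:P05067-2", "uniprotkb:P05067"))))$records
  out3 <- dedupe_and_deloop(rec3)
  expect_equal(out3$report$selfloops_removed, 1L)
  out3k <- dedupe_and_deloop(rec3, collapse_isoforms = FALSE)
  expect_equal(unname(out3k$edges), cbind("P05067", "P05067-2"))
})

test_that("assemble_network performs the two-step seed expansion", {
  # step 1 keeps seed-incident edges; Y, Z never enter V1
  e1 <- rbind(c("S1", "X"), c("X", "Y"), c("Y", "Z"))
  out <- assemble_network(e1, seeds = "S1")
  expect_equal(sort(igraph::V(out$network)$name), c("S1", "X"))
  expect_equal(igraph::ecount(out$network), 1L)
  expect_equal(out$report$nodes_after_seed_step, 2L)

  # step 2 adds edges between V1 members (X-Y here)
  e2 <- rbind(c("S1", "X"), c("S2", "Y"), c("X", "Y"))
  out2 <- assemble_network(e2, seeds = c("S1", "S2"))
  expect_equal(igraph::vcount(out2$network), 4L)
  expect_equal(igraph::ecount(out2$network), 3L)
  expect_equal(out2$report$edges_after_seed_step, 2L)

  expect_error(assemble_network(e1, seeds = character(0)), "empty-input")
  expect_error(assemble_network(e1, seeds = "NOPE"), "empty-network")
})

test_that("filtering is order-stable: permuting input rows leaves edges and tallies unchanged", {
  net <- generate_scale_free(15, 2, seed = 3)
  f <- tempfile()
  write_mitab(net, contamination_spec(2, 2, 2, 3), seed = 5, path = f)
  lines <- readLines(f)
  ref <- curate_mitab(f, seeds = NULL)
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    writeLines(c(lines[1L], sample(lines[-1L])), f)
    got <- curate_mitab(f, seeds = NULL)
    expect_identical(igraph::as_edgelist(got$network),
                     igraph::as_edgelist(ref$network))
    expect_identical(got$report[c("rows_nonhuman_removed", "rows_nonprotein_removed",
                                  "selfloops_removed", "duplicates_removed")],
                     ref$report[c("rows_nonhuman_removed", "rows_nonprotein_removed",
                                  "selfloops_removed", "duplicates_removed")])
  }
})

test_that("assembled networks are always simple", {
  for (seed in 1:5) {
    net <- generate_scale_free(20, 2, seed = seed)
    f <- tempfile()
    write_mitab(net, contamination_spec(1, 1, 2, 3), seed = seed, path = f)
    g <- curate_mitab(f, seeds = NULL)$network
    expect_true(igraph::is_simple(g))
    unlink(f)
  }
})

test_that("label_nodes applies categories, defaults to other, rejects conflicts", {
  net <- protein_network(rbind(c("P05067", "P37840"), c("P37840", "Q99999")))
  cats <- list(in_vivo_amyloid = "P05067", in_vitro_amyloid = "P37840")
  out <- label_nodes(net, cats)
  got <- stats::setNames(igraph::V(out)$category, igraph::V(out)$name)
  expect_equal(got[["P05067"]], "in_vivo_amyloid")
  expect_equal(got[["P37840"]], "in_vitro_amyloid")
  expect_equal(got[["Q99999"]], "other")
  expect_error(label_nodes(net, list(in_vivo_amyloid = "P05067",
                                     in_vitro_amyloid = c("P05067", "P37840"))),
               "conflicting-category")
})

test_that("packaged seed tables carry the curated accessions", {
  seeds <- amyloid_seed_proteins()
  expect_equal(nrow(seeds$in_vivo), 28L)
  expect_equal(nrow(seeds$related), 13L)
  expect_true("P05067" %in% seeds$in_vivo$accession)   # amyloid beta A4
  expect_true("P02766" %in% seeds$in_vivo$accession)   # transthyretin
  expect_true("P37840" %in% seeds$related$accession)   # alpha-synuclein
  expect_equal(sum(seeds$related$category == "in_vitro_amyloid"), 10L)
  expect_false(anyDuplicated(c(seeds$in_vivo$accession, seeds$related$accession)) > 0)
})
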