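# Small in-code fixtures shared across test files.

write_tmp_tsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# packaged fixture: published miRNA -> target lists as a target_map plus
# the matching family map
fixture_target_map <- function() {
  read_target_map(clp_example("mirna_clp_targets.tsv"))
}

fixture_family_map <- function() {
  load_family_map(clp_example("mirna_families.tsv"))
}

# enrichment-row layout for the fixture with every miRNA treated as one row
# (used where the published rollup is reproduced without re-testing)
fixture_enrichment_rows <- function() {
  tm <- fixture_target_map()
  fm <- fixture_family_map()
  mirna_enrichment(tm, tm$universe, family_map = fm, fdr_threshold = 1)
}

# a three-prediction-source + one-validation-source interaction table
example_interaction_files <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  pred <- file.path(dir, "predicted.tsv")
  writeLines(c(
    "source\tmirna\tgene\tvalidated",
    "predA\thsa-miR-1\tGENE1\tfalse",
    "predA\thsa-miR-1\tGENE2\tfalse",
    "predA\thsa-miR-2\tGENE3\tfalse",
    "predB\thsa-miR-1\tGENE1\tfalse",
    "predB\thsa-miR-2\tGENE3\tfalse",
    "predC\thsa-miR-1\tGENE1\tfalse",
    "predC\thsa-miR-1\tGENE3\tfalse"
  ), pred)
  val <- file.path(dir, "validated.tsv")
  writeLines(c(
    "source\tmirna\tgene\tvalidated",
    "tarbase\thsa-miR-1\tGENE1\ttrue",
    "tarbase\thsa-miR-2\tGENE3\ttrue"
  ), val)
  c(pred, val)
}

# minimal PED/MAP writer for hand-constructed trios; gts is a character
# vector of PED lines (without genotypes aligned automatically)
write_ped_map <- function(ped_lines, map_lines) {
  list(ped = write_tmp_tsv(ped_lines, ".ped"),
       map = write_tmp_tsv(map_lines, ".map"))
}
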