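# Shared HMMER fixture: one small synthetic family and its materialised
# registry, built once per test run and reused by every engine-dependent test.

.engine_cache <- new.env(parent = emptyenv())

engine_fixture <- function() {
  if (is.null(.engine_cache$fx)) {
    fam <- gen_families(family_spec(n_per_class = 3L, seed = 401L))
    dir <- file.path(tempdir(), "gh9_engine_fixture")
    registry <- build_loocv_registry(fam, dir)
    faa <- file.path(dir, "family.faa")
    write_fasta(fam, faa)
    .engine_cache$fx <- list(fam = fam, registry = registry, dir = dir, faa = faa)
  }
  .engine_cache$fx
}
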