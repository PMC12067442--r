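# The full enumeration is deterministic but takes a few seconds; cache it
# once per test run and share across test files.

.enum_cache <- new.env(parent = emptyenv())

full_skeleton_set <- function() {
  if (is.null(.enum_cache$skeletons)) {
    .enum_cache$skeletons <- generate_all_skeletons(5:7)
  }
  .enum_cache$skeletons
}

full_scaffold_set <- function() {
  if (is.null(.enum_cache$scaffolds)) {
    t0 <- proc.time()[["elapsed"]]
    .enum_cache$scaffolds <- enumerate_all(full_skeleton_set())
    .enum_cache$elapsed <- proc.time()[["elapsed"]] - t0
  }
  .enum_cache$scaffolds
}

full_enumeration_seconds <- function() {
  full_scaffold_set()
  .enum_cache$elapsed
}
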