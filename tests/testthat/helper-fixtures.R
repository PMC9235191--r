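# memoized shared fixtures so several test files can reuse one generation
.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function(n = 500, seed = 7) {
  key <- sprintf("fx_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_toy_genome(n, seed = seed)
  .fixture_cache[[key]]
}

shared_fixture_db <- function(n = 500, seed = 7) {
  key <- sprintf("db_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    tr <- shared_fixture(n, seed)
    att <- attach_hits(transcript_index(tr$transcripts), tr$hits)
    .fixture_cache[[key]] <- build_database(tr$transcripts, att)
  }
  .fixture_cache[[key]]
}
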