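# Shared fixtures, generated once per test run into tempdir().

shared_bundle_dir <- function() {
  d <- file.path(tempdir(), "cnvcurate-test-bundle")
  if (!file.exists(file.path(d, "genes.tsv"))) generate_resource_bundle(d, seed = 42)
  d
}

shared_bundle <- local({
  env <- new.env()
  function() {
    if (is.null(env$b)) env$b <- load_resources(shared_bundle_dir())
    env$b
  }
})

shared_caller_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$d)) {
      env$d <- file.path(tempdir(), "cnvcurate-test-callers")
      env$expected <- generate_caller_vcfs(env$d, seed = 42)
    }
    list(dir = env$d, expected = env$expected)
  }
})

# A small random call table for property tests.
random_calls <- function(n, seed, caller = "lumpy") {
  set.seed(seed)
  start <- sort(sample.int(9e6, n))
  len <- sample(c(60L, 300L, 2000L, 50000L, 200000L), n, replace = TRUE)
  cnv_calls(chrom = sample(c("1", "2"), n, replace = TRUE),
            start = start, end = start + len,
            type = sample(c("DEL", "DUP"), n, replace = TRUE),
            caller = caller, qual = stats::runif(n, 0, 1000),
            genotype = "0/1", filter = "PASS", ft = "PASS",
            metrics = list(pytorP1 = stats::runif(n), Q0 = stats::runif(n),
                           pytorRD = stats::runif(n, 0, 2)))
}

# Map a clustering result back onto the input rows as a partition vector.
partition_of <- function(merged, calls) {
  got <- integer(nrow(calls))
  for (ci in seq_len(nrow(merged))) {
    mem <- merged$members[[ci]]
    for (k in seq_len(nrow(mem))) {
      idx <- which(calls$chrom == mem$chrom[k] & calls$start == mem$start[k] &
                   calls$end == mem$end[k] & calls$caller == mem$caller[k])
      got[idx] <- ci
    }
  }
  got
}

same_partition <- function(a, b) {
  length(a) == length(b) && all(outer(a, a, "==") == outer(b, b, "=="))
}
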