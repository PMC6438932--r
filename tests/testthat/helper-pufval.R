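# shared fixtures built in code

dims <- puf_dimensions()

# a random but valid PUF (ratings on [1,100], allocations on [0,100])
random_puf <- function(seed, level2_mapping = "share_of_swing") {
  set.seed(seed)
  puf(swing = runif(5, 1, 100), allocation = runif(5, 0, 100),
      level2_mapping = level2_mapping)
}

# answer function replaying a fixed A/B pattern
pattern_answers <- function(pattern) {
  i <- 0
  function(state) {
    i <<- i + 1
    pattern[i]
  }
}

# minimal conformant record
make_record <- function(id = "r1", swing = c(100, 80, 80, 90, 82),
                        allocation = rep(50, 5), ...) {
  respondent_record(
    respondent_id = id,
    ranking = list("PD", c("MO", "AD"), "SC", "UA"),
    swing = swing,
    allocation = allocation,
    ...
  )
}
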