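# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_mol <- function() fixture("toy_mol", make_toy_two_arm)

toy_ss1 <- function() fixture("toy_ss1", function() {
  mol <- toy_mol()
  sweep_state_space(mol, toy_hinges(mol)[1])
})

toy_ss2 <- function() fixture("toy_ss2", function() {
  mol <- toy_mol()
  sweep_state_space(mol, toy_hinges(mol))
})

toy_ss2_small <- function() fixture("toy_ss2_small", function() {
  mol <- toy_mol()
  sweep_state_space(mol, toy_hinges(mol, steps = 5))
})

# circular distance between angles on a 90-degree torus
dist_mod90 <- function(a, b) {
  d <- abs((a - b) %% 90)
  pmin(d, 90 - d)
}
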