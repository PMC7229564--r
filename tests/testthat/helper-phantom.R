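# Shared phantom fixtures, generated once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

default_phantom <- function() fixture("phantom", function() generate_phantom(phantom_spec()))

noiseless_phantom <- function() {
  fixture("phantom0", function() generate_phantom(phantom_spec(noise_sigma = 0)))
}

default_edges <- function() {
  fixture("edges", function() detect_edges(default_phantom()$image))
}
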