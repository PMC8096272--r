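# Shared fixtures: all synthetic, built in code at test time.

wtCfg <- TetherConfig()
mutCfg <- TetherConfig("mut", "KCl")
defPrm <- SimParams()

# reduced force grid covering both transitions, for faster ensemble tests
shortGrid <- seq(0.05, 1.2, by = 0.01)

# wrap a bare extension vector into a Trace at 300 Hz
makeTrace <- function(ext, rate = 300, force = 1, turns = 0) {
  new("Trace", force = force, turns = turns,
      time = (seq_along(ext) - 1) / rate, extension = as.numeric(ext),
      meta = list())
}

# wrap force/variance vectors into a VarianceProfile
makeProfile <- function(force, variance, meanExt = rep(0, length(force)),
                        window = 4, turns = -40) {
  new("VarianceProfile", force = force, variance = variance,
      meanExtension = meanExt, window = window, turns = turns, meta = list())
}
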