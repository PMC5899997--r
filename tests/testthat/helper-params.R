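# Shared fixture builders for the simulator tests.

# GatingParams with selective overrides of the wild-type defaults.
makeParams <- function(...) {
  p <- wildTypeParams()
  ov <- list(...)
  for (nm in names(ov)) slot(p, nm) <- ov[[nm]]
  p
}

# Short activation-style protocol: hold then a single voltage-varying step.
stepProtocol <- function(stepVoltages, stepMs = 20, holdMs = 5,
                         dt = 0.005, holding = -80) {
  voltageProtocol("step", holding,
                  data.frame(label = c("hold", "test"),
                             voltage_mV = c(holding, NA),
                             duration_ms = c(holdMs, stepMs)),
                  sweepValues = stepVoltages, sweepDim = "voltage",
                  sampleIntervalMs = dt)
}

# Closed-form instantaneous-gating peak current (pA): both gates at their
# steady state for the step voltage.
instantPeak <- function(params, capacitancepF, V) {
  mInfP <- steadyStateGate(V, params@actV12mV, params@actSlopemV,
                           "increasing")            # = m_inf^p by design
  hInfV <- steadyStateGate(V, params@inactV12mV, params@inactSlopemV,
                           "decreasing")
  params@gmaxDensity * capacitancepF * mInfP * hInfV * (V - params@eRevmV)
}
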