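# Shared fixtures: the control-condition kinetics used throughout (macro
# parameters V_T = 0.87, BP_ND = 1.85 with k2 = 0.4, k4 = 0.15 /min).

ctrlParams <- function(Vb = 0) {
    kineticParams(K1 = 0.4 * 0.87 / 2.85, k2 = 0.4, k3 = 1.85 * 0.15,
                  k4 = 0.15, Vb = Vb)
}

ctrlTac <- function(Vb = 0, alpha = 0, seed = NULL) {
    simulateTAC(ctrlParams(Vb), defaultInputParams(), defaultFrameSchedule(),
                noiseModel(alpha = alpha), seed = seed)
}

# ODE oracle for the two-tissue system, independent of the closed-form path:
# dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2 ; dC2/dt = k3 C1 - k4 C2
odeModelCurve <- function(params, input, times, parent = NULL) {
    cp <- function(t) occuPET:::.cpAt(input, t, parent)
    rhs <- function(t, y, p) {
        list(c(p["K1"] * cp(t) - (p["k2"] + p["k3"]) * y[1] + p["k4"] * y[2],
               p["k3"] * y[1] - p["k4"] * y[2]))
    }
    pv <- coef(params)
    sol <- deSolve::ode(c(0, 0), c(0, times), rhs, pv[1:4], method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    ct <- sol[-1, 2] + sol[-1, 3]
    (1 - params@Vb) * ct +
        params@Vb * occuPET:::.cwbAt(input, times)
}
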