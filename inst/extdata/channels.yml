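# Voltage-gated channel library (Hodgkin-Huxley form).
#
# Each gate x evolves as dx/dt = (x_inf(V) - x)/tau_x(V) with
#   x_inf(V) = 1 / (1 + exp(-(V - vhalf)/k))          (k < 0: inactivation)
#   tau_x(V) = base + amp / (exp((V-vpeak)/kl) + exp(-(V-vpeak)/kr))   [ms]
# and the channel current density is g * prod(x^exponent) * (V - erev).
# Reversal potentials: E_Na = 50 mV, E_K = -77 mV.

na_t:
  erev: 50.0
  gates:
    m:
      exponent: 3
      inf: {vhalf: -32.0, k: 6.0}
      tau: {base: 0.04, amp: 0.25, vpeak: -38.0, kl: 12.0, kr: 12.0}
    h:
      exponent: 1
      inf: {vhalf: -49.0, k: -3.0}
      tau: {base: 0.5, amp: 14.0, vpeak: -58.0, kl: 12.0, kr: 14.0}

na_p:
  erev: 50.0
  gates:
    m:
      exponent: 1
      inf: {vhalf: -42.0, k: 5.0}
      tau: {base: 1.0, amp: 0.0}

kdrf:
  erev: -77.0
  gates:
    n:
      exponent: 4
      inf: {vhalf: -14.0, k: 8.0}
      tau: {base: 0.6, amp: 3.0, vpeak: -25.0, kl: 15.0, kr: 15.0}

kdrf_faster:
  erev: -77.0
  gates:
    n:
      exponent: 4
      inf: {vhalf: -14.0, k: 7.0}
      tau: {base: 0.3, amp: 1.8, vpeak: -35.0, kl: 10.0, kr: 30.0}

kdrs:
  erev: -77.0
  gates:
    n:
      exponent: 2
      inf: {vhalf: -25.0, k: 12.0}
      tau: {base: 20.0, amp: 80.0, vpeak: -40.0, kl: 25.0, kr: 25.0}

ka:
  erev: -77.0
  gates:
    a:
      exponent: 4
      inf: {vhalf: -37.0, k: 10.0}
      tau: {base: 0.5, amp: 1.5, vpeak: -40.0, kl: 20.0, kr: 20.0}
    b:
      exponent: 1
      inf: {vhalf: -45.0, k: -6.0}
      tau: {base: 20.0, amp: 60.0, vpeak: -75.0, kl: 15.0, kr: 15.0}
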