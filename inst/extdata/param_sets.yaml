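# Standard working points of the delayed cortico-thalamic oscillator.
#
# Shared constants: transmission delay tau (s), damping rate gamma (1/s),
# and the firing-rate nonlinearity coefficients. The quadratic curvature is
# set to 0, which keeps the cubic-order center-manifold reduction free of
# second-order corrections; the cubic term is saturating (-1), which makes
# the Hopf bifurcation supercritical and the attractor globally bounded.
#
# The control parameter is the delayed feedback gain b: the rest state
# destabilizes as b decreases through b_c (stronger negative cortico-
# thalamic feedback). a is the instantaneous cortico-cortical gain.
#   b_c(a = 0.6) = -1.1085178887, omega_c = 5.52217412 rad/s (0.879 Hz)
#   b_c(a = -1.4) = -2.3787212088, omega_c = 8.00927050 rad/s (1.275 Hz)
# A and B sit at the same offset mu = b_c - b = 0.03 above their respective
# critical points (equal amplitudes); B oscillates ~45% faster than A,
# a mismatch large enough for mutual coupling to quench both rhythms.
# C shares a with A but lies far above the curve (mu = 7.0): its waveform
# carries strong 5th-harmonic content from the weakly damped second delay
# mode, which is what supports five-fold multimodal phase locking.
delay: 0.3
damping: 10.0
nl2: 0.0
nl3: -1.0
sets:
- label: A
  gain_a: 0.6
  gain_b: -1.1385178887
- label: B
  gain_a: -1.4
  gain_b: -2.4087212088
- label: C
  gain_a: 0.6
  gain_b: -8.1085178887
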