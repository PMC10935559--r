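# Pathological bench configuration: lateral tibial attachment with the
# default tendon springs. The analytic order-5 backend is the recommended
# one for calibration workflows.
schema: 1
femur_attach: medial
tibia_attach: lateral
quad_K: 156
quad_L0: 0.1432
pat_K: 629
pat_L0: 0.0714
backend: "analytic:5"
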