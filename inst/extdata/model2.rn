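# Reduced SAC network: seven species, nine reactions.  Obtained from the
# full network by lumping species into Activator / Inhibitor / Promotor
# classes; the Promotor (APC/C) is activated by the Activator and blocked
# by the Inhibitor.
@species KinU KinA Activator Inhibitor Promotor Promotor_A Promotor_I
KinU -> KinA ; 0.01 ; attachment
Activator + KinU -> KinU + Inhibitor ; 1.0 ; inhibition
Inhibitor -> Activator ; 0.1 ; relaxation
Activator + Promotor -> Promotor_A ; 1.0 ; activation
Promotor_A -> Activator + Promotor ; 0.1 ; deactivation
Inhibitor + Promotor -> Promotor_I ; 1.0 ; blocking
Promotor_I -> Inhibitor + Promotor ; 0.1 ; unblocking
Inhibitor + Promotor_A -> Promotor_I + Activator ; 1.0 ; displacement
Promotor_I -> Promotor_A + Inhibitor ; 0.01 ; slippage
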