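# Coarsest SAC network: four species, three reactions.
# Attachment converts unattached kinetochores; unattached kinetochores
# catalyse conversion of the Activator into the Inhibitor; the Inhibitor
# relaxes back spontaneously.
@species KinU KinA Activator Inhibitor
KinU -> KinA ; 0.01 ; attachment
Activator + KinU -> KinU + Inhibitor ; 1.0 ; inhibition
Inhibitor -> Activator ; 0.1 ; relaxation
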