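# Full SAC network: 14 species, 21 reactions, covering the Mad2 template
# mechanism, mitotic checkpoint complex (MCC) assembly, and activation /
# inhibition of the anaphase promoting complex (APC/C).  Reconstructed
# from the published network diagram; the organization counts (16 at the
# long timescale, 64 for the pro-metaphase variant) validate the
# reconstruction.
@species KinU KinA O-Mad2 C-Mad2 Cdc20 Cdc20:Mad2 BubR1:Bub3 MCC Cdc20:BubR1:Bub3 APC/C APC/C:Cdc20 APC/C:MCC APC/C:Cdc20:C-Mad2 APC/C:Cdc20:BubR1:Bub3
KinU -> KinA ; 0.01 ; attachment
KinU + O-Mad2 -> KinU + C-Mad2 ; 1.0 ; template
C-Mad2 + Cdc20 -> Cdc20:Mad2 ; 1.0 ; mad2_cdc20_binding
Cdc20:Mad2 + BubR1:Bub3 -> MCC ; 1.0 ; mcc_assembly
MCC + APC/C -> APC/C:MCC ; 1.0 ; apc_inhibition
Cdc20 + APC/C -> APC/C:Cdc20 ; 1.0 ; apc_activation
APC/C:Cdc20 -> Cdc20 + APC/C ; 0.1 ; apc_deactivation
APC/C:Cdc20 + C-Mad2 -> APC/C:Cdc20:C-Mad2 ; 1.0 ; apc_mad2_binding
O-Mad2 -> ; 0.01 ; omad2_decay
C-Mad2 -> O-Mad2 ; 0.1 ; mad2_relaxation
Cdc20:Mad2 -> O-Mad2 + Cdc20 ; 0.1 ; mad2_cdc20_release
MCC -> Cdc20:Mad2 + BubR1:Bub3 ; 0.1 ; mcc_dissociation
APC/C:MCC -> MCC + APC/C ; 0.1 ; apc_mcc_release
APC/C:MCC -> APC/C:Cdc20 + C-Mad2 + BubR1:Bub3 ; 0.05 ; apc_mcc_disassembly
APC/C:Cdc20:C-Mad2 -> APC/C:Cdc20 + O-Mad2 ; 0.1 ; apc_mad2_release
APC/C:Cdc20:BubR1:Bub3 -> APC/C:Cdc20 + BubR1:Bub3 ; 0.1 ; bbc_release
Cdc20 + BubR1:Bub3 -> Cdc20:BubR1:Bub3 ; 1.0 ; bbc_assembly
KinA + Cdc20:BubR1:Bub3 -> KinA + Cdc20 + BubR1:Bub3 ; 1.0 ; kin_bbc_dissociation
APC/C + Cdc20:BubR1:Bub3 -> APC/C:Cdc20 + BubR1:Bub3 ; 1.0 ; apc_cdc20_extraction
APC/C + Cdc20:BubR1:Bub3 -> APC/C:Cdc20:BubR1:Bub3 ; 0.5 ; apc_bbc_capture
APC/C:Cdc20:BubR1:Bub3 -> APC/C ; 0.05 ; apc_bbc_turnover
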