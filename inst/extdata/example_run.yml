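# Example end-to-end simulation config (all fields optional; defaults in
# default_e2e_config()).
seed: 1
image_size: 16
n_exams: [60, 60]
n_test: 60
pos_fraction: 0.3
signal_strength: 8
n_horizontal: 2
central_epochs: 4
server_mode: honest     # honest | tamper_bitflip | tamper_iv_xor | replay | drop
optimizer: adam
lr: 0.005
weight_decay: 0.0001
pretrain: yes
pretrain_epochs: 2
flip_rate: 0
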