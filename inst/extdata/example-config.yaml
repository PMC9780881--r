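# Example configuration: a short conduction run at 96% filter length.
# Absent keys take the protocol defaults (dt 0.25 fs, 310 K, 4 ns
# thermalization, injection 5/ps, thermostat 1/ps, driving 100 mV).
duration_ns: 0.5
thermalization_ns: 0.05
length_fraction: 0.96
seed: 2024
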