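substance,pnec_ug_per_kg,citation
nano-TiO2,1000,"soil predicted no-effect concentration for nano-TiO2"
CNT,176,"soil predicted no-effect concentration for carbon nanotubes"
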