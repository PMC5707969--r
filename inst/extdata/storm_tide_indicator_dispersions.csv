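series,dispersion
mariculture_loss,1.4547
coastal_engineering_loss,1.4778
death_toll,13.3995
ship_loss,1.1552
collapsed_home_loss,3.4671
storm_surge_frequency,1.0942
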