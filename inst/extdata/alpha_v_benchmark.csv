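structure,calc,exp,temp_range_K
MNPHOL_mc,211.9,214.6,95-350
ETDIAM_Ia,270.5,193.0,130-274
FURHUV_b,187.3,154.6,100-218
GLURAC_b,164.6,206.6,120-373
HXACAN_I,154.4,156.9,20-330
ADIPAC_I,173.8,198.4,100-293
DPYRAM_mc,178.9,164.8,150-293
PYRZIN_b,155.3,181.1,90-293
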