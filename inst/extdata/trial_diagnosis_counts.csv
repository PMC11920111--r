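site,arm,diagnosed,n
Ulm,imaging,87,107
Ulm,soc,69,109
Leiden,imaging,84,89
Leiden,soc,71,88
Coimbra,imaging,3,79
Coimbra,soc,2,75
UK,imaging,56,128
UK,soc,51,127
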