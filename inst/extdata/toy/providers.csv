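provider_id,provider_type
PRV1,CSC
PRV2,PSC
PRV3,SRH
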