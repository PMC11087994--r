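label,covered
first_new_service,700472
second_new_service,122665
both_new_services,823137
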