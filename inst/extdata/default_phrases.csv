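kind,pattern,scope,direction
negation,not a candidate for,mention_window,forward
negation,no plans? for,mention_window,forward
negation,expired (before|prior to) receiving,mention_window,forward
negation,died (before|prior to) receiving,mention_window,forward
negation,never (received|started|given),mention_window,forward
negation,did not (receive|start|get|tolerate),mention_window,forward
negation,ineligible for,mention_window,forward
negation,"(recommended|offered|advised).{0,15}but (pt |patient )?(refused|declined)",mention_window,backward
negation,but (pt |patient )?(refused|declined),mention_window,backward
negation,refused,mention_window,both
negation,declined,mention_window,both
negation,was not (given|administered|started),mention_window,backward
negation,not administered,mention_window,backward
negation,"held, not given",mention_window,backward
uncertainty,unknown (if|whether) (ever )?given,mention_window,both
uncertainty,unclear (if|whether) (given|received),mention_window,both
uncertainty,possibly (received|given),mention_window,both
uncertainty,may have (received|been given),mention_window,both
no_treatment,(pt|patient) refused( all)?( systemic)? (treatment|chemo(therapy)?),whole_record,forward
no_treatment,refused all treatment,whole_record,forward
no_treatment,opted for hospice,whole_record,forward
no_treatment,\bhospice\b,whole_record,forward
no_treatment,comfort (care|measures)( only)?,whole_record,forward
no_treatment,best supportive care,whole_record,forward
no_treatment,no (systemic )?(treatment|chemo(therapy)?|therapy)( was)?( given| administered| planned| received| recommended)?,whole_record,forward
no_treatment,(died|expired) before (any )?(treatment|chemo(therapy)?),whole_record,forward
no_treatment,(pt|patient) (declined|refused) (further )?(care|intervention),whole_record,forward
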