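a
an
the
and
or
of
in
on
at
to
for
with
without
from
by
as
is
are
was
were
be
been
no
not
there
this
that
these
those
it
its
per
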